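view,visit,n_features
metabolomics_pos,12M,68
clinical,6M,25
genus_16s,baseline,145
microbial_protein,baseline,2435
immune,6M,58
metabolomics_neg,6M,77
metabolomics_pos,6M,68
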