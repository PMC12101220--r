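model,statistic,set1,set2,set3,set4,set5,mean,sd
approach1_best_late,auc,0.633,0.842,0.716,0.752,0.517,0.692,0.123
approach1_best_late,sensitivity,0.857,0.867,0.800,0.714,0.667,0.781,0.088
approach1_best_late,specificity,0.500,0.667,0.435,0.565,0.250,0.483,0.156
approach2_best_late,auc,0.667,1.000,0.800,1.000,0.875,0.868,0.141
approach2_best_late,sensitivity,0.250,1.000,0.800,1.000,0.800,0.770,0.307
approach2_best_late,specificity,0.667,0.875,0.571,0.857,0.500,0.694,0.168
approach1_early,auc,0.531,0.611,0.549,0.689,0.463,0.569,0.086
approach1_early,sensitivity,0.786,0.733,0.933,0.857,0.533,0.769,0.152
approach1_early,specificity,0.273,0.375,0.261,0.522,0.500,0.386,0.123
approach2_early,auc,0.542,0.875,0.686,0.964,0.500,0.713,0.203
approach2_early,sensitivity,0.750,0.800,1.000,1.000,0.600,0.830,0.172
approach2_early,specificity,0.333,0.750,0.429,0.286,0.500,0.460,0.182
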