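# shared fixture builders; everything is generated in code

make_ft <- function(m, modality = "npx", name = "toy") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  feature_table(m, modality, name)
}

random_ft <- function(n = 20, p = 50, modality = "npx", seed = 1,
                      counts = FALSE) {
  set.seed(seed)
  m <- if (counts) matrix(rpois(n * p, 4), n, p)
       else matrix(rnorm(n * p), n, p)
  make_ft(m, modality)
}

# a separable toy: feature f01 is a noisy copy of the label
separable_xy <- function(n = 40, p = 8, seed = 1, noise = 0.05) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  x[, 1] <- y + rnorm(n, sd = noise)
  list(x = x, y = y)
}

# meta for n subjects (first n_pos positive), possibly several visits
toy_meta <- function(n = 12, n_pos = 5, visits = "v1") {
  subj <- sprintf("S%02d", seq_len(n))
  outc <- rep(c("persistent", "outgrown"), c(n_pos, n - n_pos))
  cohort_meta(sample_id = as.vector(outer(subj, visits, paste, sep = "_")),
              subject_id = rep(subj, length(visits)),
              visit = rep(visits, each = n),
              outcome = rep(outc, length(visits)))
}

# small multi-view cohort for pipeline tests
small_cohort <- function(effect = 2, seed = 1, n_subjects = 39,
                         n_positive = 15, n_views = 2, p = 25,
                         n_informative = 5, visits = c("baseline", "6M")) {
  mods <- rep(c("npx", "counts", "metabolite", "clinical"),
              length.out = n_views)
  vs <- lapply(seq_len(n_views), function(i)
    view_spec(paste0("view", letters[i]), mods[i], p,
              n_informative = n_informative, effect_size = effect,
              zero_frac = if (mods[i] %in% c("counts", "intensity")) 0.3 else 0,
              censor_frac = if (mods[i] == "metabolite") 0.1 else 0))
  generate_cohort(cohort_spec(n_subjects, n_positive, visits = visits,
                              view_specs = vs, seed = seed))
}
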