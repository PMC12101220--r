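#' Specify one synthetic view
#'
#' @param name view name.
#' @param modality `"counts"` (compositional sequencing counts),
#'   `"intensity"` (zero-inflated log-normal intensities, e.g. iBAQ),
#'   `"npx"` (complete Gaussian log-scale panel values),
#'   `"metabolite"` (log-normal with left-censored missingness) or
#'   `"clinical"` (half continuous, half integer-coded categorical).
#' @param n_features number of features.
#' @param n_informative number of class-informative features
#'   (`<= n_features`).
#' @param effect_size standardized between-class mean shift on
#'   informative features (log scale for counts), `>= 0`.
#' @param zero_frac structural zero fraction for counts/intensity
#'   views, in \[0, 1).
#' @param censor_frac left-censored missing fraction for metabolite
#'   views, in \[0, 1).
#' @param depth multinomial sequencing depth per sample (counts only).
#' @param visit_effect multiplier applied to `effect_size` per visit
#'   (recycled); lets signal be concentrated at specific visits.
#' @return an object of class `view_spec`.
#' @export
view_spec <- function(name, modality, n_features, n_informative = 0,
                      effect_size = 0, zero_frac = 0, censor_frac = 0,
                      depth = 10000, visit_effect = 1) {
  modality <- match.arg(modality, ft_modalities())
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (zero_frac < 0 || zero_frac >= 1) stop("zero_frac must be in [0, 1)")
  if (censor_frac < 0 || censor_frac >= 1)
    stop("censor_frac must be in [0, 1)")
  structure(list(name = name, modality = modality,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, zero_frac = zero_frac,
                 censor_frac = censor_frac, depth = as.integer(depth),
                 visit_effect = visit_effect),
            class = "view_spec")
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the emulated study design: 39 subjects of whom 15
#' carry the positive (persistent) outcome, sampled at baseline, 6 and
#' 12 months.
#'
#' @param n_subjects total subjects (default 39).
#' @param n_positive subjects in the positive class (default 15).
#' @param visits visit labels (default `c("baseline", "6M", "12M")`).
#' @param view_specs list of [view_spec()]s (default:
#'   [default_view_specs()]).
#' @param subject_corr correlation of a subject's latent effect across
#'   visits, in \[0, 1\] (default 0.5).
#' @param seed integer seed; generation is fully reproducible.
#' @param drop_cell optional list `(view, visit, subject)` marking one
#'   sample of one view as entirely missing, emulating a lost sample.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 39, n_positive = 15,
                        visits = c("baseline", "6M", "12M"),
                        view_specs = default_view_specs(),
                        subject_corr = 0.5, seed = 1, drop_cell = NULL) {
  if (n_positive >= n_subjects)
    stop("n_positive must be smaller than n_subjects")
  if (subject_corr < 0 || subject_corr > 1)
    stop("subject_corr must be in [0, 1]")
  stopifnot(all(vapply(view_specs, inherits, logical(1), "view_spec")))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_positive = as.integer(n_positive),
                 visits = visits, view_specs = view_specs,
                 subject_corr = subject_corr, seed = as.integer(seed),
                 drop_cell = drop_cell),
            class = "cohort_spec")
}

#' Default view set of the emulated study
#'
#' Eight modalities with the study's feature dimensions: clinical (25),
#' 16S genus counts (145), microbial protein intensities (2435), human
#' protein intensities (207), immune panel (58), metabolomics negative
#' (77) and positive (68) mode, bile/fatty acids (22).  `scale` shrinks
#' all dimensions proportionally (minimum 8 features) for fast tests.
#'
#' @param scale multiplier on feature counts in (0, 1\].
#' @param n_informative,effect_size shared signal settings per view.
#' @return list of [view_spec()]s.
#' @export
default_view_specs <- function(scale = 1, n_informative = 5,
                               effect_size = 1) {
  dims <- c(clinical = 25, genus_16s = 145, microbial_protein = 2435,
            human_protein = 207, immune = 58, metabolomics_neg = 77,
            metabolomics_pos = 68, bile_fatty_acids = 22)
  modal <- c(clinical = "clinical", genus_16s = "counts",
             microbial_protein = "intensity", human_protein = "intensity",
             immune = "npx", metabolomics_neg = "metabolite",
             metabolomics_pos = "metabolite", bile_fatty_acids = "metabolite")
  lapply(names(dims), function(v) {
    p <- max(8L, round(dims[[v]] * scale))
    view_spec(v, modal[[v]], n_features = p,
              n_informative = min(n_informative, p),
              effect_size = effect_size,
              zero_frac = if (modal[[v]] %in% c("counts", "intensity"))
                0.3 else 0,
              censor_frac = if (modal[[v]] == "metabolite") 0.1 else 0)
  })
}

#' Generate a synthetic multi-view cohort
#'
#' Produces one [feature_table()] per (view, visit) pair plus a
#' [cohort_meta()].  Shared structure: each subject-visit carries a
#' latent Gaussian effect `z = sqrt(rho) u_subject + sqrt(1-rho) e`,
#' giving within-subject correlation `rho` across visits; every view
#' loads on it, which is what grouped splitting must respect.
#' Counts views are Dirichlet-multinomial compositions whose
#' informative concentrations differ between classes by `effect_size`
#' on the log scale; intensity/npx/metabolite views are Gaussian on the
#' log scale with a class mean shift of `effect_size` (in sd units) on
#' informative features; metabolite views are left-censored at the
#' per-feature `censor_frac` quantile (values below become missing);
#' clinical views discretize half of their columns into 4-level codes.
#'
#' @param spec a [cohort_spec()].
#' @return list with `tables` (named `"<view>_<visit>"`), `meta`
#'   (a [cohort_meta()]) and `manifest` (data.frame: view, visit,
#'   modality, table name).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  subjects <- sprintf("S%03d", seq_len(n))
  visits <- spec$visits
  rng_scope(spec$seed, {
    pos <- sample(subjects, spec$n_positive)
    outcome <- ifelse(subjects %in% pos, "persistent", "outgrown")
    cls <- as.integer(subjects %in% pos)  # 1 = positive class

    # latent subject effect, correlated across visits
    u <- stats::rnorm(n)
    z <- sapply(seq_along(visits), function(v)
      sqrt(spec$subject_corr) * u +
        sqrt(1 - spec$subject_corr) * stats::rnorm(n))
    rownames(z) <- subjects

    tables <- list()
    manifest <- NULL
    for (vs in spec$view_specs) {
      ve <- rep_len(vs$visit_effect, length(visits))
      per_visit <- simulate_view(vs, cls, z, effect_mults = ve)
      for (vi in seq_along(visits)) {
        tab <- per_visit[[vi]]
        rownames(tab) <- paste(subjects, visits[vi], sep = "_")
        nm <- paste(vs$name, visits[vi], sep = "_")
        tables[[nm]] <- feature_table(tab, vs$modality, name = nm)
        manifest <- rbind(manifest, data.frame(
          view = vs$name, visit = visits[vi], modality = vs$modality,
          table = nm, stringsAsFactors = FALSE))
      }
    }

    if (!is.null(spec$drop_cell)) {
      dc <- spec$drop_cell
      nm <- paste(dc$view, dc$visit, sep = "_")
      if (is.null(tables[[nm]])) stop("drop_cell names an unknown view/visit")
      sid <- paste(dc$subject, dc$visit, sep = "_")
      v <- values(tables[[nm]])
      v <- v[rownames(v) != sid, , drop = FALSE]
      tables[[nm]] <- ft_replace(tables[[nm]], v)
    }

    meta <- cohort_meta(
      sample_id = as.vector(outer(subjects, visits, paste, sep = "_")),
      subject_id = rep(subjects, length(visits)),
      visit = rep(visits, each = n),
      outcome = rep(outcome, length(visits)))
    list(tables = tables, meta = meta, manifest = manifest)
  })
}

# all visits of one view at once: feature-level parameters (baseline
# abundances, latent-effect loadings) are drawn once and shared across
# visits, so the subject latent effect induces the configured
# cross-visit correlation.  `z` is the subjects x visits latent
# matrix; returns a list of samples x features matrices, one per
# visit.  Uses the current RNG stream.
simulate_view <- function(vs, cls, z, effect_mults) {
  n <- length(cls)
  p <- vs$n_features
  informative <- seq_len(vs$n_informative)
  fnames <- sprintf("%s_f%03d", vs$name, seq_len(p))

  if (vs$modality == "counts") {
    # Dirichlet-multinomial: class shifts informative log-concentrations
    log_alpha <- stats::rnorm(p, mean = 0, sd = 1)
    load <- stats::rnorm(p, sd = 0.3)
    out <- lapply(seq_len(ncol(z)), function(vi) {
      eff <- vs$effect_size * effect_mults[vi]
      m <- matrix(0, n, p)
      for (i in seq_len(n)) {
        la <- log_alpha + load * z[i, vi]
        if (cls[i] == 1L) la[informative] <- la[informative] + eff
        conc <- exp(la) * 5  # concentration scale: moderate overdispersion
        g <- stats::rgamma(p, shape = conc, rate = 1)
        if (vs$zero_frac > 0)
          g[stats::runif(p) < vs$zero_frac] <- 0
        if (all(g == 0)) g[sample.int(p, 1L)] <- 1
        m[i, ] <- stats::rmultinom(1, vs$depth, g / sum(g))
      }
      m
    })
  } else {
    mu <- stats::rnorm(p, mean = if (vs$modality == "metabolite") 10 else 0,
                       sd = 2)
    load <- stats::rnorm(p, sd = 0.5)
    cat_cols <- if (vs$modality == "clinical" && p >= 2)
      seq_len(floor(p / 2)) else integer(0)
    out <- lapply(seq_len(ncol(z)), function(vi) {
      eff <- vs$effect_size * effect_mults[vi]
      m <- matrix(stats::rnorm(n * p), n, p)
      m <- sweep(m, 2L, mu, "+") + outer(z[, vi], load)
      if (eff > 0)
        m[cls == 1L, informative] <- m[cls == 1L, informative] + eff
      for (j in cat_cols)  # integer-coded categoricals
        m[, j] <- findInterval(m[, j], stats::quantile(
          m[, j], c(0.25, 0.5, 0.75)))
      if (vs$modality == "intensity") {
        m <- 2^m  # raw positive intensities
        if (vs$zero_frac > 0)
          m[matrix(stats::runif(n * p) < vs$zero_frac, n, p)] <- 0
      }
      if (vs$modality == "metabolite") {
        m <- 2^m  # raw scale; censoring applied on raw values
        if (vs$censor_frac > 0) {
          for (j in seq_len(p)) {
            cut <- stats::quantile(m[, j], vs$censor_frac, type = 1)
            m[m[, j] <= cut, j] <- NA_real_
          }
        }
      }
      m
    })
  }
  lapply(out, function(m) { colnames(m) <- fnames; m })
}

#' Write a generated cohort to disk
#'
#' One CSV per (view, visit) table, plus `meta.csv` and
#' `manifest.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort$tables))
    write_feature_table(cohort$tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  utils::write.csv(as.data.frame(cohort$meta), file.path(dir, "meta.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
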