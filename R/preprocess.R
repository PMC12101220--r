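#' Aggregate features into groups (e.g. ASVs to genera)
#'
#' Column-sums member features into their group; total counts are
#' preserved.  Missing values propagate as missing only if every member
#' of a group is missing for that sample; otherwise missing members are
#' treated as 0 (counts semantics).
#'
#' @param table a [feature_table()].
#' @param mapping named character vector: names are feature ids of
#'   `table`, values the group each feature belongs to.
#' @return a [feature_table()] with one column per distinct group, in
#'   first-appearance order of the mapping.
#' @export
aggregate_taxa <- function(table, mapping) {
  v <- values(table)
  unmapped <- setdiff(colnames(v), names(mapping))
  if (length(unmapped))
    stop("features without a group: ", paste(unmapped, collapse = ", "))
  grp <- mapping[colnames(v)]
  groups <- unique(unname(grp))
  out <- vapply(groups, function(g) {
    sub <- v[, grp == g, drop = FALSE]
    all_na <- rowSums(!is.na(sub)) == 0L
    s <- rowSums(sub, na.rm = TRUE)
    s[all_na] <- NA_real_
    s
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(v), groups))
  colnames(out) <- groups
  rownames(out) <- rownames(v)
  ft_replace(table, out)
}

#' Drop features whose total over all samples is below a minimum
#'
#' The low-count rule for genus tables and iBAQ protein intensities:
#' features with `sum over samples < min_total` (strict) are removed,
#' as is anything on the explicit exclusion list (e.g. known
#' contaminant protein groups identified upstream).
#'
#' @param table a [feature_table()].
#' @param min_total minimum column total to survive (default 3).
#' @param exclude feature ids to drop unconditionally.
#' @return the filtered [feature_table()]; survivor order preserved.
#' @export
filter_low_total <- function(table, min_total = 3, exclude = character()) {
  v <- values(table)
  totals <- colSums(v, na.rm = TRUE)
  keep <- totals >= min_total & !(colnames(v) %in% exclude)
  if (!any(keep)) warning("all features removed by low-total filter")
  ft_replace(table, v[, keep, drop = FALSE])
}

#' Robust centered log-ratio transform
#'
#' Per sample (row), every positive entry x becomes
#' `log(x) - mean(log(positive entries of the row))`; zeros are not
#' shifted by a pseudocount but become missing in the output.  Output
#' rows are scale-invariant and have mean zero over non-missing
#' entries.
#'
#' @param table a [feature_table()] with non-negative values.  Existing
#'   missing entries stay missing and are ignored in the row geometric
#'   mean.
#' @return the transformed [feature_table()].
#' @export
rclr <- function(table) {
  v <- values(table)
  if (any(v < 0, na.rm = TRUE)) stop("rclr needs non-negative values")
  pos <- !is.na(v) & v > 0
  if (any(rowSums(pos) == 0L))
    stop("rclr: sample(s) with no positive entries: ",
         paste(rownames(v)[rowSums(pos) == 0L], collapse = ", "))
  lv <- suppressWarnings(log(v))
  lv[!pos] <- NA_real_
  gm <- rowMeans(lv, na.rm = TRUE)
  ft_replace(table, lv - gm)
}

#' Limit-of-detection filter
#'
#' Drops features observed below their limit of detection in more than
#' `max_frac` of the samples (strict `>`; a feature at exactly the
#' boundary is kept).  Missing entries count as below LOD.
#'
#' @param table a [feature_table()].
#' @param lod per-feature detection limit: single number or named
#'   vector over feature ids.
#' @param max_frac tolerated below-LOD fraction (default 0.2).
#' @return the filtered [feature_table()].
#' @export
lod_filter <- function(table, lod, max_frac = 0.2) {
  v <- values(table)
  if (length(lod) == 1L) {
    lodv <- rep(lod, ncol(v))
  } else {
    miss <- setdiff(colnames(v), names(lod))
    if (length(miss)) stop("no LOD given for: ", paste(miss, collapse = ", "))
    lodv <- unname(lod[colnames(v)])
  }
  below <- sweep(v, 2L, lodv, "<")
  below[is.na(below)] <- TRUE
  frac <- colMeans(below)
  ft_replace(table, v[, frac <= max_frac, drop = FALSE])
}

#' Missingness filter
#'
#' Drops features missing in more than `max_frac` of the samples
#' (strict `>`).
#'
#' @inheritParams lod_filter
#' @return the filtered [feature_table()].
#' @export
missingness_filter <- function(table, max_frac = 0.2) {
  v <- values(table)
  frac <- colMeans(is.na(v))
  ft_replace(table, v[, frac <= max_frac, drop = FALSE])
}

#' Normalize each sample by a per-sample weight
#'
#' Divides each row by its (dry sample) weight.
#'
#' @param table a [feature_table()].
#' @param weights positive numbers: one per sample, either unnamed in
#'   table order or named by sample id.
#' @return the normalized [feature_table()].
#' @export
weight_normalize <- function(table, weights) {
  v <- values(table)
  if (!is.null(names(weights))) {
    miss <- setdiff(rownames(v), names(weights))
    if (length(miss)) stop("no weight for sample(s): ",
                           paste(miss, collapse = ", "))
    weights <- unname(weights[rownames(v)])
  }
  if (length(weights) != nrow(v)) stop("need one weight per sample")
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive and finite")
  ft_replace(table, v / weights)
}

#' Log2 transform
#'
#' Applied to non-missing entries only; a non-missing entry that is not
#' strictly positive is an error (censored values should already be
#' missing at this point).
#'
#' @param table a [feature_table()].
#' @return the transformed [feature_table()].
#' @export
log2_transform <- function(table) {
  v <- values(table)
  if (any(v <= 0, na.rm = TRUE))
    stop("log2_transform: non-positive values present; censor or filter first")
  ft_replace(table, log2(v))
}

#' Impute left-censored missing values (QRILC)
#'
#' Missingness is assumed left-censored: a value is missing because it
#' fell below the detection limit.  Per feature, a normal distribution
#' is fitted by regressing the observed order statistics on their
#' standard-normal quantiles.  Since the missing values are assumed to
#' be the lowest ones, the observed values are treated as the top
#' `m` of `n` order statistics (plotting positions `(n - m + i)/(n + 1)`),
#' and the regression is restricted to the upper `tail_quantile` share
#' of the observed points, where the normal model is least distorted by
#' censoring.  The intercept estimates the mean, the slope the sd.
#' Missing entries are replaced by random draws from the fitted normal
#' truncated above at the feature's observed minimum.
#'
#' @param table a [feature_table()] on a log scale.
#' @param tail_quantile fraction of the (upper) observed order
#'   statistics used in the fit (default 0.75).
#' @param seed integer; draws use a private RNG stream.
#' @return the completed [feature_table()] (no missing values).
#' @details Features with fewer than 3 observed values cannot support a
#'   per-feature fit; they are imputed from a fit pooled over all
#'   observed values in the table, with a warning.
#' @export
qrilc_impute <- function(table, tail_quantile = 0.75, seed = 1) {
  v <- values(table)
  if (!anyNA(v)) return(table)
  fit_one <- function(obs, n_total) qrilc_fit(obs, n_total, tail_quantile)
  all_obs <- v[!is.na(v)]
  global <- fit_one(all_obs, length(v))
  out <- v
  rng_scope(seed, {
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      if (!any(nas)) next
      obs <- v[!nas, j]
      if (length(obs) < 3L) {
        warning(sprintf(
          "feature '%s' has <3 observed values; imputing from global fit",
          colnames(v)[j]))
        fit <- global
        upper_lim <- if (length(obs)) min(obs) else stats::qnorm(
          0.05, global["mean"], global["sd"])
      } else {
        fit <- fit_one(obs, nrow(v))
        upper_lim <- min(obs)
      }
      out[nas, j] <- truncnorm::rtruncnorm(
        sum(nas), a = -Inf, b = upper_lim, mean = fit["mean"], sd = fit["sd"])
    }
  })
  ft_replace(table, out)
}

# Fit a normal to left-censored data from the observed order
# statistics.  The `m` observed values are taken to be the top m of
# `n_total` order statistics (plotting positions (n - m + i)/(n + 1));
# regressing them on the matching standard-normal quantiles over the
# upper `tail_quantile` share of the observed points gives the mean
# (intercept) and sd (slope).
qrilc_fit <- function(obs, n_total, tail_quantile = 0.75) {
  m <- length(obs)
  p <- (n_total - m + seq_len(m)) / (n_total + 1)
  q <- stats::qnorm(p)
  x <- sort(obs)
  upper <- seq.int(max(1L, ceiling((1 - tail_quantile) * m) + 1L), m)
  if (length(upper) < 2L) upper <- seq_len(m)
  co <- stats::coef(stats::lm(x[upper] ~ q[upper]))
  c(mean = unname(co[1]), sd = max(unname(co[2]), 1e-8))
}

#' Near-zero-variance filter
#'
#' Drops features that are (a) constant over the samples, or (b) nearly
#' constant: frequency ratio of the two most common values >= 19
#' (i.e. 95/5) AND fraction of unique values < 10%.  These are the
#' conventional defaults of the resampling toolchains this filter
#' mirrors.
#'
#' @param table a [feature_table()].
#' @param freq_ratio,unique_frac the two cutoffs.
#' @return list with `table` (filtered) and `kept` (feature ids), so
#'   the training-set decision can be replayed on a test table via
#'   [keep_features()].
#' @export
nzv_filter <- function(table, freq_ratio = 19, unique_frac = 0.1) {
  v <- values(table)
  keep <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[!is.na(v[, j]), j]
    if (length(unique(x)) <= 1L) return(FALSE)
    tab <- sort(table(x), decreasing = TRUE)
    fr <- if (length(tab) >= 2L) tab[1] / tab[2] else Inf
    uf <- length(tab) / length(x)
    !(fr >= freq_ratio && uf < unique_frac)
  }, logical(1))
  list(table = ft_replace(table, v[, keep, drop = FALSE]),
       kept = colnames(v)[keep])
}

#' Greedy high-correlation filter
#'
#' Repeatedly finds the feature pair with the largest absolute Pearson
#' correlation above `cutoff` and drops the member with the larger mean
#' absolute correlation to all other remaining features, until no pair
#' exceeds the cutoff.
#'
#' @param table a [feature_table()].
#' @param cutoff absolute-correlation threshold (default 0.9, strict
#'   `>`).
#' @return list with `table` and `kept` as in [nzv_filter()].
#' @export
correlation_filter <- function(table, cutoff = 0.9) {
  v <- values(table)
  cm <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  cm <- abs(cm)
  alive <- rep(TRUE, ncol(v))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (!length(sub) || max(sub) <= cutoff) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    ids <- which(alive)[hit]
    mean_abs <- rowMeans(cm[ids, alive, drop = FALSE])
    drop_id <- ids[which.max(mean_abs)]
    alive[drop_id] <- FALSE
  }
  list(table = ft_replace(table, v[, alive, drop = FALSE]),
       kept = colnames(v)[alive])
}

#' Subset a table to a fixed feature list
#'
#' Applies a training-set filter decision (from [nzv_filter()] or
#' [correlation_filter()]) to another table.
#'
#' @param table a [feature_table()].
#' @param kept feature ids to keep (all must be present).
#' @return the subset [feature_table()].
#' @export
keep_features <- function(table, kept) {
  v <- values(table)
  miss <- setdiff(kept, colnames(v))
  if (length(miss)) stop("features absent from table: ",
                         paste(miss, collapse = ", "))
  ft_replace(table, v[, kept, drop = FALSE])
}

#' Median imputation fitted on training data
#'
#' The completion shim for tree learners: RCLR leaves zeros undefined,
#' so remaining missing entries are filled with the per-feature median
#' of the *training* observations.  Fit on the training table, apply to
#' any table with the same features.
#'
#' @param table the training [feature_table()].
#' @return an object of class `median_imputer`; apply with
#'   [impute_median()].
#' @export
fit_median_impute <- function(table) {
  v <- values(table)
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0  # feature entirely missing in training
  structure(list(medians = med), class = "median_imputer")
}

#' @rdname fit_median_impute
#' @param imputer a fitted `median_imputer`.
#' @export
impute_median <- function(table, imputer) {
  v <- values(table)
  miss <- setdiff(colnames(v), names(imputer$medians))
  if (length(miss)) stop("imputer has no median for: ",
                         paste(miss, collapse = ", "))
  for (j in colnames(v)) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- imputer$medians[[j]]
  }
  ft_replace(table, v)
}

# Evaluate `expr` under a private RNG state seeded by `seed`,
# restoring the caller's RNG afterwards.
rng_scope <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
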