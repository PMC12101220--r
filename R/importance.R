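#' Permutation variable importance on the test set
#'
#' For every feature of every selected view: the feature's column in a
#' copy of that view's (imputation-completed) test table is shuffled
#' (within the test set, without replacement), the view's
#' probabilities and the combined ensemble AUC are recomputed, and the
#' decrease from the baseline test AUC is recorded.  This is repeated `n_perm` times; the mean
#' decrease and its sd summarize how much the ensemble's
#' generalization relies on the feature.  The baseline AUC is computed
#' once and shared by all features.
#'
#' @param view_models named list of `view_model`s (the selected views).
#' @param test_tables named list of test [feature_table()]s, matching
#'   `view_models`.
#' @param prob_matrix samples x views matrix of unpermuted test
#'   probabilities for the selected views (as used for evaluation;
#'   `NA` allowed).
#' @param labels binary test labels aligned with the rows of
#'   `prob_matrix`.
#' @param weights weights of the selected views.
#' @param sample_map optional named vector mapping a view table's
#'   sample ids to the row ids of `prob_matrix` (identity by default;
#'   used when rows are subjects but tables are subject-visit).
#' @param n_perm number of permutations (default 100, must be >= 2).
#' @param seed integer seed.
#' @return data.frame with columns `view`, `feature`,
#'   `mean_decrease`, `sd_decrease`, `important`
#'   (`mean_decrease > 0.01`), sorted by decreasing mean.
#' @export
permutation_importance <- function(view_models, test_tables, prob_matrix,
                                   labels, weights, sample_map = NULL,
                                   n_perm = 100, seed = 1) {
  if (n_perm < 2) stop("n_perm must be at least 2")
  stopifnot(identical(names(view_models), names(test_tables)),
            identical(names(view_models), colnames(prob_matrix)))
  baseline <- auc(labels, combine_probs(prob_matrix, weights))
  rows <- rownames(prob_matrix)
  out <- NULL
  for (vi in seq_along(view_models)) {
    vn <- names(view_models)[vi]
    vm <- view_models[[vn]]
    tab <- test_tables[[vn]]
    # complete (imputed) matrix once; the shuffle permutes the column
    # the forest actually sees
    x <- values(impute_median(tab, vm$imputer))[, vm$model$features,
                                                drop = FALSE]
    map <- if (is.null(sample_map)) stats::setNames(rownames(x), rownames(x))
           else sample_map
    ridx <- match(map[rownames(x)], rows)
    for (j in seq_along(vm$model$features)) {
      feat <- vm$model$features[j]
      if (length(unique(x[, j])) <= 1L) {
        dec <- rep(0, n_perm)  # shuffling a constant is the identity
      } else {
        pp <- .rf_predict_perm_cpp(vm$model$trees, x, j - 1L,
                                   as.integer(n_perm),
                                   as.integer(seed + 9973L * vi + j))
        pm <- prob_matrix
        dec <- vapply(seq_len(n_perm), function(i) {
          pm[ridx, vn] <- pp[, i]
          baseline - auc(labels, combine_probs(pm, weights))
        }, numeric(1))
      }
      out <- rbind(out, data.frame(
        view = vn, feature = feat, mean_decrease = mean(dec),
        sd_decrease = stats::sd(dec), stringsAsFactors = FALSE))
    }
  }
  out$important <- out$mean_decrease > 0.01
  out[order(-out$mean_decrease), , drop = FALSE]
}

#' Gini (mean decrease in node impurity) importance of a view model
#'
#' Training-set importance straight from the fitted forest: the total
#' Gini impurity decrease attributed to splits on each feature,
#' averaged over trees.  Reported for context; permutation importance
#' on the test set is the headline measure.
#'
#' @param view_model a `view_model` (or an `rf_model`).
#' @param top_n return only the `top_n` highest-scoring features
#'   (default `Inf` = all).
#' @return named numeric vector, sorted decreasing.
#' @export
gini_importance <- function(view_model, top_n = Inf) {
  imp <- if (inherits(view_model, "view_model"))
    view_model$model$importance else view_model$importance
  imp <- sort(imp, decreasing = TRUE)
  utils::head(imp, top_n)
}

#' Aggregate permutation importance across train/test repeats
#'
#' Merges per-repeat importance tables by (view, feature), takes the
#' grand mean of the per-repeat mean decreases (a feature absent from
#' a repeat — e.g. its view was not selected there — contributes 0),
#' and applies the strict `> 0.01` importance rule to the grand mean.
#'
#' @param records list of data.frames from [permutation_importance()],
#'   one per repeat.
#' @return data.frame with `view`, `feature`, one `repeat<i>_decrease`
#'   column per repeat, `mean_decrease`, `important`; sorted by
#'   decreasing grand mean.
#' @export
aggregate_importance <- function(records) {
  stopifnot(length(records) >= 1L)
  keys <- unique(do.call(rbind, lapply(records, function(r)
    r[, c("view", "feature")])))
  per_rep <- vapply(records, function(r) {
    m <- match(paste(keys$view, keys$feature),
               paste(r$view, r$feature))
    d <- r$mean_decrease[m]
    d[is.na(d)] <- 0
    d
  }, numeric(nrow(keys)))
  if (is.null(dim(per_rep))) per_rep <- matrix(per_rep, nrow = nrow(keys))
  colnames(per_rep) <- sprintf("repeat%d_decrease", seq_along(records))
  out <- cbind(keys, as.data.frame(per_rep),
               mean_decrease = rowMeans(per_rep))
  out$important <- out$mean_decrease > 0.01
  out[order(-out$mean_decrease), , drop = FALSE]
}
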