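#' Default random-forest hyperparameters
#'
#' The conventional defaults: `mtry = floor(sqrt(n_features))`
#' (at least 1) and `ntree = 500`.
#'
#' @param n_features number of features in the view.
#' @return list with `mtry` and `ntree`.
#' @export
default_hyperparams <- function(n_features) {
  list(mtry = max(1L, as.integer(floor(sqrt(n_features)))), ntree = 500L)
}

#' Default tuning grid
#'
#' `mtry` at one half, one and two times the square-root default
#' (clamped to `[1, n_features]`, deduplicated) crossed with
#' `ntree` 500 and 1000.
#'
#' @param n_features number of features.
#' @return list with `mtry` and `ntree` vectors.
#' @export
default_tune_grid <- function(n_features) {
  m0 <- default_hyperparams(n_features)$mtry
  mtry <- unique(pmin(pmax(c(floor(m0 / 2), m0, 2 * m0), 1L), n_features))
  list(mtry = as.integer(mtry), ntree = c(500L, 1000L))
}

#' Train (and optionally tune) one view's classifier
#'
#' Evaluates every `(mtry, ntree)` grid point by grouped k-fold
#' cross-validation: for each fold, a forest is fitted on the
#' out-of-fold training samples (after median imputation fitted on
#' those samples only) and predicts the held-in fold.  A grid point's
#' score is the AUC of the *pooled* out-of-fold predictions — with two
#' dozen training subjects, per-fold AUCs are too unstable to average.
#' Ties prefer smaller `mtry`, then smaller `ntree`.  The winner is
#' refitted on the full training table; its CV AUC is stored as
#' `train_auc` and the winning out-of-fold probabilities are kept for
#' decision-threshold selection.
#'
#' @param table training [feature_table()] (post-preprocessing; may
#'   still contain missing entries, which the median-impute shim
#'   fills).
#' @param labels binary outcome per training sample (positive =
#'   persistent).
#' @param folds named integer vector mapping each *sample id* of
#'   `table` to a CV fold.
#' @param mtry_grid,ntree_grid candidate values; defaults are the
#'   single square-root/500 point (no tuning).
#' @param seed integer seed for all forest fits.
#' @param resample `"none"` (default), `"oversample"` or `"smote"`,
#'   applied to each fold's training part and to the final refit.
#' @return an object of class `view_model`: `model` (an `rf_model`),
#'   `mtry`, `ntree`, `train_auc`, `oof_probs` (named by sample id),
#'   `imputer`, `features`, `name`.
#' @export
tune_and_train <- function(table, labels, folds, mtry_grid = NULL,
                           ntree_grid = NULL, seed = 1,
                           resample = c("none", "oversample", "smote")) {
  resample <- match.arg(resample)
  v <- values(table)
  p <- ncol(v)
  if (is.null(mtry_grid)) mtry_grid <- default_hyperparams(p)$mtry
  if (is.null(ntree_grid)) ntree_grid <- default_hyperparams(p)$ntree
  mtry_grid <- pmin(pmax(as.integer(mtry_grid), 1L), p)
  sid <- rownames(v)
  miss <- setdiff(sid, names(folds))
  if (length(miss)) stop("no fold for sample(s): ",
                         paste(miss, collapse = ", "))
  fold <- folds[sid]
  y <- as_binary(labels)

  fit_part <- function(xtr, ytr_raw, mtry, ntree, fit_seed) {
    imp <- fit_median_impute(ft_wrap(xtr, table))
    xtr_c <- values(impute_median(ft_wrap(xtr, table), imp))
    ytr <- ytr_raw
    if (resample != "none") {
      rs <- if (resample == "oversample")
        random_oversample(xtr_c, ytr_raw, seed = fit_seed)
      else smote(xtr_c, ytr_raw, seed = fit_seed)
      xtr_c <- rs$x; ytr <- rs$y
    }
    list(model = random_forest(xtr_c, ytr, ntree = ntree, mtry = mtry,
                               seed = fit_seed),
         imputer = imp)
  }

  grid <- expand.grid(mtry = sort(unique(mtry_grid)),
                      ntree = sort(unique(ntree_grid)))
  scores <- numeric(nrow(grid))
  oof_by_point <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    oof <- rep(NA_real_, nrow(v))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L)
        stop(sprintf("fold %d leaves a single-class training set", f))
      part <- fit_part(v[tr, , drop = FALSE], labels[tr],
                       grid$mtry[g], grid$ntree[g],
                       fit_seed = seed + 131L * f + 7L * g)
      xte <- values(impute_median(ft_wrap(v[!tr, , drop = FALSE], table),
                                  part$imputer))
      oof[!tr] <- predict(part$model, xte)
    }
    scores[g] <- auc(y, oof)
    oof_by_point[[g]] <- oof
  }
  best <- order(-scores, grid$mtry, grid$ntree)[1L]

  final <- fit_part(v, labels, grid$mtry[best], grid$ntree[best],
                    fit_seed = seed)
  structure(list(model = final$model, imputer = final$imputer,
                 mtry = grid$mtry[best], ntree = grid$ntree[best],
                 train_auc = scores[best],
                 oof_probs = stats::setNames(oof_by_point[[best]], sid),
                 cv_grid = cbind(grid, cv_auc = scores),
                 features = colnames(v), name = table$name),
            class = "view_model")
}

ft_wrap <- function(m, proto) feature_table(m, proto$modality, proto$name)

#' @export
print.view_model <- function(x, ...) {
  cat(sprintf("<view_model> %s: mtry %d, ntree %d, CV AUC %.3f\n",
              x$name, x$mtry, x$ntree, x$train_auc))
  invisible(x)
}

#' Predict positive-class probabilities from a view model
#'
#' Applies the training-set median imputer, then the fitted forest.
#'
#' @param object a `view_model`.
#' @param table a [feature_table()] containing the training features.
#' @param ... unused.
#' @return named probability vector (one entry per sample).
#' @export
predict.view_model <- function(object, table, ...) {
  v <- values(table)[, object$features, drop = FALSE]
  x <- values(impute_median(ft_wrap(v, table), object$imputer))
  predict(object$model, x)
}
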