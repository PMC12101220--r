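#' Random forest classifier for binary outcomes
#'
#' A compact classification forest tailored to the small-n, wide-p
#' tables this package works with: trees are grown to purity on
#' bootstrap samples of the rows, each split chooses the best of `mtry`
#' randomly drawn candidate features by the Gini criterion, and the
#' predicted probability of the positive class is the mean over trees of
#' the terminal node's positive-class fraction.  Fits are reproducible
#' given `seed` and independent of R's global RNG.
#'
#' @param x complete numeric matrix (samples x features); no `NA`s.
#' @param y binary labels (see [auc()] for accepted encodings); the
#'   positive class is the second factor level / `1`.
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split; default
#'   `floor(sqrt(ncol(x)))`.
#' @param min_node smallest node size that may still be split further
#'   minus one; 1 grows trees to purity.
#' @param seed integer seed for the forest's private RNG stream.
#' @return an object of class `rf_model` with elements `trees`
#'   (opaque), `importance` (named mean-decrease-in-Gini per feature),
#'   `mtry`, `ntree`, `features`.
#' @export
random_forest <- function(x, y, ntree = 500, mtry = NULL, min_node = 1,
                          seed = 1) {
  if (anyNA(x)) stop("x must be complete; impute missing values first")
  yb <- as_binary(y)
  if (length(unique(yb)) < 2L) stop("y must contain both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_fit_cpp(x, yb, as.integer(ntree), as.integer(mtry),
                     as.integer(min_node), as.integer(seed))
  structure(list(trees = fit$trees,
                 importance = stats::setNames(fit$importance, colnames(x)),
                 mtry = as.integer(mtry), ntree = as.integer(ntree),
                 features = colnames(x)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, %d features\n",
              x$ntree, x$mtry, length(x$features)))
  invisible(x)
}

#' Predicted probability of the positive class
#'
#' @param object an `rf_model`.
#' @param newdata numeric matrix with (at least) the training features
#'   as columns; reordered by name when column names are present.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.rf_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss))
      stop("newdata lacks training features: ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("newdata has the wrong number of columns")
  }
  if (anyNA(newdata)) stop("newdata must be complete")
  p <- .rf_predict_cpp(object$trees, newdata)
  stats::setNames(p, rownames(newdata))
}
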