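#' AUC-proportional ensemble weights
#'
#' `W_i = AUC_i / sum_j AUC_j`: a view with a better cross-validated
#' training AUC contributes proportionally more to the combined
#' probability.
#'
#' @param train_aucs positive numbers, one per view; names are kept.
#' @return weights summing to 1.
#' @export
compute_weights <- function(train_aucs) {
  if (length(train_aucs) == 0L) stop("no AUCs supplied")
  if (any(!is.finite(train_aucs) | train_aucs <= 0))
    stop("all AUCs must be positive")
  train_aucs / sum(train_aucs)
}

#' Combine per-view probabilities into an ensemble probability
#'
#' Weighted sum of the per-view predicted probabilities.  When a
#' sample is missing from some views (e.g. a lost specimen), the
#' weights are renormalized over the views that did score it — this is
#' the practical advantage of late integration over concatenation,
#' which would require complete data.
#'
#' @param prob_matrix samples x views matrix of positive-class
#'   probabilities; `NA` where a view did not score a sample.
#' @param weights per-view weights (see [compute_weights()]), aligned
#'   with the columns.
#' @return named vector of combined probabilities.
#' @export
combine_probs <- function(prob_matrix, weights) {
  if (is.null(dim(prob_matrix)))
    prob_matrix <- matrix(prob_matrix, ncol = 1L)
  if (ncol(prob_matrix) != length(weights))
    stop("one weight per view required")
  avail <- !is.na(prob_matrix)
  if (any(rowSums(avail) == 0L))
    stop("sample(s) scored by no view: ",
         paste(rownames(prob_matrix)[rowSums(avail) == 0L], collapse = ", "))
  wm <- matrix(weights, nrow(prob_matrix), length(weights), byrow = TRUE)
  wm[!avail] <- 0
  p0 <- prob_matrix
  p0[!avail] <- 0
  out <- rowSums(p0 * wm) / rowSums(wm)
  stats::setNames(out, rownames(prob_matrix))
}

#' Select the ensemble decision threshold
#'
#' For every candidate threshold, each view's *training* sensitivity
#' and specificity are computed from its out-of-fold CV probabilities;
#' the threshold maximizing the geometric mean of all these values
#' (2 numbers per view, pooled jointly) is chosen.  Ties prefer the
#' threshold closest to 0.5, then the smaller one.  If every candidate
#' scores zero (some view never gets one class right at any
#' threshold), 0.5 is returned with a warning.
#'
#' @param oof_probs list of named out-of-fold probability vectors, one
#'   per view (from [tune_and_train()]).
#' @param labels named binary training labels (by sample id).
#' @param grid candidate thresholds (default `seq(0.05, 0.95, 0.01)`).
#' @param pooling `"joint"` pools all views' sensitivities and
#'   specificities into one geometric mean; `"per_view"` averages the
#'   per-view geometric means instead.
#' @return the selected threshold.
#' @export
select_threshold <- function(oof_probs, labels,
                             grid = seq(0.05, 0.95, by = 0.01),
                             pooling = c("joint", "per_view")) {
  pooling <- match.arg(pooling)
  if (!length(grid)) stop("empty threshold grid")
  score_one <- function(thr) {
    ss <- lapply(oof_probs, function(p) {
      sens_spec(labels[names(p)], p, thr)
    })
    if (pooling == "joint") geometric_mean(unlist(ss))
    else mean(vapply(ss, geometric_mean, numeric(1)))
  }
  scores <- vapply(grid, score_one, numeric(1))
  if (all(scores == 0)) {
    warning("all geometric means are zero; falling back to threshold 0.5")
    return(0.5)
  }
  best <- which(scores == max(scores))
  best[order(abs(grid[best] - 0.5), grid[best])][1L] -> pick
  grid[pick]
}

#' Classify from combined probabilities
#'
#' Positive (persistent) iff the combined probability is greater than
#' or equal to the threshold; the boundary counts as positive.
#'
#' @param probs combined probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return factor with levels `c("outgrown", "persistent")`.
#' @export
classify <- function(probs, threshold = 0.5) {
  factor(ifelse(probs >= threshold, "persistent", "outgrown"),
         levels = c("outgrown", "persistent"))
}

#' Concatenate views column-wise (early integration)
#'
#' Joins feature tables on sample id, prefixing feature ids with the
#' view name so they stay unique.  Tables with unequal sample sets are
#' inner-joined with a warning.
#'
#' @param tables named list of [feature_table()]s.
#' @param modality modality tag of the result (default `"clinical"`,
#'   i.e. "mixed"; the tag is informational here).
#' @return one concatenated [feature_table()].
#' @export
concatenate_views <- function(tables, modality = "clinical") {
  stopifnot(length(tables) >= 1L)
  nms <- names(tables) %||% paste0("view", seq_along(tables))
  common <- Reduce(intersect, lapply(tables, sample_ids))
  if (!length(common)) stop("no samples shared by all views")
  if (any(vapply(tables, function(t) length(sample_ids(t)), integer(1)) !=
          length(common)))
    warning("unequal sample sets; inner join on ", length(common), " samples")
  mats <- mapply(function(t, nm) {
    v <- values(t)[common, , drop = FALSE]
    colnames(v) <- paste(nm, colnames(v), sep = ".")
    v
  }, tables, nms, SIMPLIFY = FALSE)
  feature_table(do.call(cbind, mats), modality = modality,
                name = paste0("concat(", paste(nms, collapse = "+"), ")"))
}
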