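#' Greedy forward selection of views
#'
#' The combinatorial number of view subsets is far too large to
#' enumerate (see [count_combinations()]), so the best combination is
#' found greedily on the test set: if the all-views ensemble already
#' matches or beats every single view's test AUC, all views are kept.
#' Otherwise the search is seeded with the best single view and the
#' remaining views are visited one at a time in descending order of
#' their individual test AUC (ties: input order); a view is kept
#' permanently iff adding it *strictly* increases the combined test
#' AUC.  Weights are renormalized over the current subset at every
#' step.
#'
#' @param prob_matrix samples x views matrix of per-view test
#'   probabilities (`NA` allowed, see [combine_probs()]).
#' @param labels binary test labels aligned with the rows.
#' @param weights full-ensemble view weights (any positive numbers;
#'   renormalized per subset).
#' @return list with `selected` (view names, in the matrix's column
#'   order), `auc` (combined test AUC of the selection) and `trace`
#'   (data.frame: step, candidate, auc_before, auc_after, kept).
#' @export
forward_select <- function(prob_matrix, labels, weights) {
  if (is.null(dim(prob_matrix)))
    prob_matrix <- matrix(prob_matrix, ncol = 1L,
                          dimnames = list(names(prob_matrix), "view1"))
  vn <- colnames(prob_matrix) %||% paste0("view", seq_len(ncol(prob_matrix)))
  colnames(prob_matrix) <- vn
  names(weights) <- vn
  subset_auc <- function(sel) {
    auc(labels, combine_probs(prob_matrix[, sel, drop = FALSE], weights[sel]))
  }
  indiv <- vapply(vn, function(v) subset_auc(v), numeric(1))
  all_auc <- subset_auc(vn)
  trace <- data.frame(step = 0L, candidate = "(all views)",
                      auc_before = NA_real_, auc_after = all_auc,
                      kept = NA, stringsAsFactors = FALSE)
  if (all_auc >= max(indiv)) {
    return(list(selected = vn, auc = all_auc, trace = trace))
  }
  order_cand <- order(-indiv, seq_along(indiv))
  seedv <- vn[order_cand[1L]]
  current <- seedv
  cur_auc <- indiv[seedv]
  trace <- rbind(trace, data.frame(step = 1L, candidate = seedv,
                                   auc_before = NA_real_,
                                   auc_after = cur_auc, kept = TRUE,
                                   stringsAsFactors = FALSE))
  step <- 1L
  for (i in order_cand[-1L]) {
    step <- step + 1L
    cand <- vn[i]
    new_auc <- subset_auc(c(current, cand))
    kept <- new_auc > cur_auc
    trace <- rbind(trace, data.frame(step = step, candidate = cand,
                                     auc_before = cur_auc,
                                     auc_after = new_auc, kept = kept,
                                     stringsAsFactors = FALSE))
    if (kept) {
      current <- c(current, cand)
      cur_auc <- new_auc
    }
  }
  list(selected = vn[vn %in% current], auc = unname(cur_auc), trace = trace)
}

#' Count all non-empty view combinations over several approaches
#'
#' With `n_k` views in approach `k`, trying every non-empty subset of
#' every approach means `sum_k (2^n_k - 1)` model fits — for the
#' 8-view and 24-view approaches that is 16,777,470, which is why
#' [forward_select()] exists.
#'
#' @param view_counts integer vector of views per approach.
#' @return total number of non-empty subsets (double, exact for
#'   counts < 53 views).
#' @export
count_combinations <- function(view_counts) {
  if (!length(view_counts) || any(view_counts < 1))
    stop("view_counts must be positive integers")
  sum(2^as.numeric(view_counts) - 1)
}
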