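#' Repeated grouped stratified train/test splits
#'
#' Splits *subjects* (never individual samples) into training and test
#' sets so that all visits of a subject land on the same side, with
#' class proportions preserved.  Per class, `round(train_frac * class
#' size)` subjects (round half up) go to training; the largest class is
#' then adjusted so the overall training count equals
#' `round(train_frac * n_subjects)` — with 39 subjects (24/15) and
#' `train_frac = 2/3` this gives the canonical 26 train / 13 test with
#' a 16/10 class split.  Within each repeat's training set, subjects
#' are dealt into `k` cross-validation folds, again stratified and
#' grouped by subject.
#'
#' @param meta a [cohort_meta()].
#' @param train_frac fraction of subjects used for training
#'   (default 2/3).
#' @param n_repeats number of independent train/test splits
#'   (default 5).
#' @param k number of CV folds within each training set (default 5).
#' @param seed integer seed; the whole plan is reproducible.
#' @return an object of class `split_plan`: list with `repeats` (each
#'   a list with `train`, `test` subject-id vectors and `folds`, a
#'   named integer fold map over training subjects) and `seed`.
#' @export
grouped_stratified_split <- function(meta, train_frac = 2 / 3,
                                     n_repeats = 5, k = 5, seed = 1) {
  outc <- subject_outcomes(meta)
  classes <- split(names(outc), outc)
  if (any(lengths(classes) < 2L))
    stop("each class needs at least 2 subjects")
  n_total <- length(outc)
  target_total <- round_half_up(train_frac * n_total)
  n_train <- vapply(classes, function(s) round_half_up(train_frac * length(s)),
                    numeric(1))
  # adjust the largest class so the global training total is hit exactly
  excess <- sum(n_train) - target_total
  if (excess != 0) {
    big <- which.max(lengths(classes))
    n_train[big] <- n_train[big] - excess
  }
  if (any(n_train < 1) || any(n_train >= lengths(classes)))
    stop("train_frac leaves a class without train or test subjects")

  reps <- rng_scope(seed, {
    lapply(seq_len(n_repeats), function(r) {
      train <- unlist(lapply(seq_along(classes), function(ci) {
        sample(classes[[ci]], n_train[ci])
      }), use.names = FALSE)
      test <- setdiff(names(outc), train)
      folds <- kfold_assign(outc[train], k)
      list(train = train, test = test, folds = folds)
    })
  })
  structure(list(repeats = reps, k = k, seed = seed), class = "split_plan")
}

round_half_up <- function(x) floor(x + 0.5)

# Stratified subject -> fold assignment.  Per class, shuffled members
# are dealt round-robin over the folds ordered by ascending current
# occupancy (random tie-break), so per-class fold counts differ by at
# most one AND total fold sizes stay balanced across classes.  Uses
# the current RNG stream.
kfold_assign <- function(outcomes, k) {
  folds <- integer(length(outcomes))
  names(folds) <- names(outcomes)
  occupancy <- integer(k)
  for (cl in levels(factor(outcomes))) {
    members <- names(outcomes)[outcomes == cl]
    if (!length(members)) next
    members <- sample(members)
    fold_order <- order(occupancy + stats::runif(k))
    assigned <- rep(fold_order, length.out = length(members))
    folds[members] <- assigned
    occupancy <- occupancy + tabulate(assigned, k)
  }
  folds
}

#' Grouped stratified k-fold assignment
#'
#' Standalone fold assignment for a set of training subjects.
#'
#' @param outcomes named factor of subject outcomes (names = subject
#'   ids).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector mapping each subject to a fold in
#'   `1:k`.
#' @export
grouped_stratified_kfold <- function(outcomes, k = 5, seed = 1) {
  rng_scope(seed, kfold_assign(outcomes, k))
}

#' Serialize a split plan to JSON for audit
#'
#' Writes (or re-reads) the full train/test/fold assignment of every
#' repeat, so a published analysis can document exactly which subjects
#' were held out where.
#'
#' @param plan a `split_plan`.
#' @param path output file.
#' @return `write_split_plan()` returns `path` invisibly;
#'   `read_split_plan()` returns a `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  payload <- list(
    repeats = lapply(plan$repeats, function(r)
      list(train = r$train, test = r$test,
           folds = as.list(r$folds))),  # named list => JSON object
    k = plan$k, seed = plan$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  reps <- lapply(raw$repeats, function(r)
    list(train = vapply(r$train, as.character, character(1),
                        USE.NAMES = FALSE),
         test = vapply(r$test, as.character, character(1),
                       USE.NAMES = FALSE),
         folds = vapply(r$folds, as.integer, integer(1))))
  structure(list(repeats = reps, k = raw$k[[1]], seed = raw$seed[[1]]),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  r1 <- x$repeats[[1]]
  cat(sprintf("<split_plan> %d repeats, %d train / %d test subjects, %d CV folds\n",
              length(x$repeats), length(r1$train), length(r1$test), x$k))
  invisible(x)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class rows, sampled with replacement, until both
#' classes have equal counts.  Applied to training data only.
#'
#' @param x numeric matrix (rows = samples).
#' @param y binary labels aligned with the rows of `x`.
#' @param seed integer seed.
#' @return list with resampled `x` and `y` (original rows first, then
#'   the duplicates).
#' @export
random_oversample <- function(x, y, seed = 1) {
  yb <- as_binary(y)
  n1 <- sum(yb == 1L); n0 <- sum(yb == 0L)
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  idx <- which(yb == minority)
  extra <- rng_scope(seed, sample(idx, need, replace = TRUE))
  list(x = rbind(x, x[extra, , drop = FALSE]),
       y = c(y, y[extra]))
}

#' SMOTE: synthetic minority oversampling
#'
#' Generates synthetic minority-class samples on the segments between a
#' minority point and one of its `k_neighbors` nearest minority-class
#' neighbors (Euclidean distance, uniform interpolation weight), until
#' class counts balance.
#'
#' @inheritParams random_oversample
#' @param k_neighbors number of nearest minority neighbors considered
#'   (default 5).  The minority class must have more than `k_neighbors`
#'   members; matching the source workflow, a smaller minority class is
#'   an explicit error rather than a silent fallback.
#' @return list with resampled `x` and `y`.
#' @export
smote <- function(x, y, k_neighbors = 5, seed = 1) {
  yb <- as_binary(y)
  n1 <- sum(yb == 1L); n0 <- sum(yb == 0L)
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) 1L else 0L
  idx <- which(yb == minority)
  if (length(idx) <= k_neighbors)
    stop("insufficient minority samples for SMOTE (need > k_neighbors = ",
         k_neighbors, ", have ", length(idx), ")")
  xm <- x[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  need <- abs(n0 - n1)
  syn <- rng_scope(seed, {
    base <- rep_len(seq_len(nrow(xm)), need)[sample(need)]
    t(vapply(base, function(i) {
      j <- nn[i, sample.int(k_neighbors, 1L)]
      u <- stats::runif(1)
      xm[i, ] + u * (xm[j, ] - xm[i, ])
    }, numeric(ncol(xm))))
  })
  colnames(syn) <- colnames(x)
  y_new <- if (is.factor(y)) {
    factor(rep(levels(y)[minority + 1L], need), levels = levels(y))
  } else rep(y[idx[1L]], need)
  list(x = rbind(x, syn), y = c(y, y_new))
}
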