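#' Construct a feature table
#'
#' A `feature_table` is the unit of data every transform and learner in
#' this package consumes: one view's samples-by-features numeric matrix
#' together with its modality tag.  Missing entries are encoded as `NA`
#' in the matrix; the missing mask is therefore `is.na(values(x))`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids; both are
#'   required and must be unique.
#' @param modality one of `"counts"`, `"intensity"`, `"npx"`,
#'   `"metabolite"`, `"clinical"`.
#' @param name optional view name (used in logs and reports).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, modality, name = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  modality <- match.arg(modality, ft_modalities())
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` needs unique row names (sample ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` needs unique column names (feature ids)")
  structure(list(values = values, modality = modality,
                 name = name %||% modality),
            class = "feature_table")
}

ft_modalities <- function() {
  c("counts", "intensity", "npx", "metabolite", "clinical")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s [%s]: %d samples x %d features, %.1f%% missing\n",
              x$name, x$modality, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Accessors for feature tables
#'
#' @param x a [feature_table()].
#' @return `values()` the numeric matrix (`NA` = missing);
#'   `missing_mask()` a logical matrix, `TRUE` where the value is
#'   missing; `sample_ids()`/`feature_ids()` the respective id vectors.
#' @export
values <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  x$values
}

#' @rdname values
#' @export
missing_mask <- function(x) is.na(values(x))

#' @rdname values
#' @export
sample_ids <- function(x) rownames(values(x))

#' @rdname values
#' @export
feature_ids <- function(x) colnames(values(x))

# replace the matrix, keeping modality/name
ft_replace <- function(x, values) {
  x$values <- values
  x
}

#' Cohort metadata
#'
#' Per-sample bookkeeping: which subject a sample belongs to, at which
#' visit it was taken, and the subject's binary outcome.  The positive
#' class is persistent allergy; the negative class is outgrowth.
#'
#' @param sample_id,subject_id,visit character vectors, one entry per
#'   sample.
#' @param outcome factor or character with levels
#'   `c("outgrown", "persistent")`; constant within subject.
#' @return a `data.frame` of class `cohort_meta`.
#' @export
cohort_meta <- function(sample_id, subject_id, visit, outcome) {
  outcome <- factor(outcome, levels = c("outgrown", "persistent"))
  if (anyNA(outcome)) stop("outcome must be 'outgrown' or 'persistent'")
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  per_subj <- tapply(as.character(outcome), subject_id,
                     function(v) length(unique(v)))
  if (any(per_subj > 1)) stop("outcome must be constant within subject")
  out <- data.frame(sample_id = as.character(sample_id),
                    subject_id = as.character(subject_id),
                    visit = as.character(visit),
                    outcome = outcome, stringsAsFactors = FALSE)
  class(out) <- c("cohort_meta", "data.frame")
  out
}

#' Subject-level outcomes from cohort metadata
#'
#' @param meta a [cohort_meta()].
#' @return named factor of outcomes, one entry per subject.
#' @export
subject_outcomes <- function(meta) {
  first <- !duplicated(meta$subject_id)
  stats::setNames(meta$outcome[first], meta$subject_id[first])
}

#' Read / write a feature table as CSV
#'
#' Plain CSV with sample ids in the first column, feature ids as the
#' header; empty cells are missing values.
#'
#' @param x a [feature_table()]; `path` file path; `modality`,`name`
#'   passed to [feature_table()] on read.
#' @return `write_feature_table()` the path, invisibly;
#'   `read_feature_table()` a [feature_table()].
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = sample_ids(x), values(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, modality, name = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  feature_table(m, modality = modality, name = name)
}
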