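#' Apply the default preprocessing recipe of a modality
#'
#' The per-modality rules, applied in a fixed order on the full table
#' (all visits) before any splitting:
#' * `counts`: low-total filter (`< 3` over all samples) then [rclr()];
#' * `intensity`: low-total (iBAQ) filter then [rclr()];
#' * `npx`: none (limit-of-detection filtering needs upstream LODs and
#'   is available separately via [lod_filter()]);
#' * `metabolite`: missingness filter (> 20%), optional dry-weight
#'   normalization, log2, then QRILC imputation;
#' * `clinical`: none.
#'
#' @param table a [feature_table()].
#' @param weights optional per-sample dry weights (metabolite only).
#' @param seed seed for the QRILC draws.
#' @return the preprocessed [feature_table()].
#' @export
apply_recipe <- function(table, weights = NULL, seed = 1) {
  switch(table$modality,
    counts = rclr(filter_low_total(table, 3)),
    intensity = rclr(filter_low_total(table, 3)),
    npx = table,
    metabolite = {
      t2 <- missingness_filter(table, 0.2)
      if (!is.null(weights)) t2 <- weight_normalize(t2, weights)
      qrilc_impute(log2_transform(t2), seed = seed)
    },
    clinical = table)
}

# Build the per-approach view tables from a cohort.
#
# Per view, the per-visit tables are stacked (rows = subject-visit
# samples, features intersected across visits) and preprocessed as one
# table.  Approach 1 then uses one such table per view (unit: sample);
# approach 2 slices each view by visit and re-keys rows to subject ids
# (unit: subject), giving `views x visits` tables.
build_views <- function(cohort, approach, seed = 1) {
  stopifnot(approach %in% c(1, 2))
  mf <- cohort$manifest
  meta <- cohort$meta
  full <- list()
  for (v in unique(mf$view)) {
    nms <- mf$table[mf$view == v]
    tabs <- cohort$tables[nms]
    common <- Reduce(intersect, lapply(tabs, feature_ids))
    stacked <- do.call(rbind, lapply(tabs, function(t)
      values(t)[, common, drop = FALSE]))
    ft <- feature_table(stacked, tabs[[1]]$modality, name = v)
    full[[v]] <- apply_recipe(ft, seed = seed)
  }
  if (approach == 1) {
    units <- meta$sample_id
    unit_subject <- stats::setNames(meta$subject_id, meta$sample_id)
    unit_labels <- stats::setNames(meta$outcome, meta$sample_id)
    return(list(tables = full, unit = "sample",
                unit_subject = unit_subject, unit_labels = unit_labels))
  }
  sample_subject <- stats::setNames(meta$subject_id, meta$sample_id)
  out <- list()
  for (v in names(full)) {
    vv <- values(full[[v]])
    visit_of <- stats::setNames(meta$visit, meta$sample_id)[rownames(vv)]
    for (vis in unique(cohort$manifest$visit)) {
      sub <- vv[which(visit_of == vis), , drop = FALSE]
      rownames(sub) <- unname(sample_subject[rownames(sub)])
      nm <- paste(v, vis, sep = "_")
      out[[nm]] <- feature_table(sub, full[[v]]$modality, name = nm)
    }
  }
  outc <- subject_outcomes(meta)
  list(tables = out, unit = "subject",
       unit_subject = stats::setNames(names(outc), names(outc)),
       unit_labels = outc)
}

#' Run the multi-view classification experiment end to end
#'
#' For each train/test repeat of the split plan: preprocess (done once
#' up front), train one random forest per view with grouped 5-fold CV
#' ([tune_and_train()]), derive AUC-proportional weights
#' ([compute_weights()]), pick the decision threshold from the pooled
#' out-of-fold training predictions ([select_threshold()]), evaluate
#' the all-views ensemble on the test set, run greedy
#' [forward_select()]ion of views, report AUC / sensitivity /
#' specificity of the selected ensemble, and (optionally) permutation
#' importance of the selected views' features.
#'
#' @param cohort list with `tables`, `meta`, `manifest` (the shape
#'   returned by [generate_cohort()]; assemble the same shape for real
#'   data).
#' @param approach 1 (one view per modality, visits stacked as rows)
#'   or 2 (one view per modality-visit pair, rows are subjects).
#' @param integration `"late"` (per-view classifiers, AUC-weighted
#'   combination) or `"early"` (all views concatenated into one table,
#'   single classifier).
#' @param n_repeats number of train/test splits (default 5).
#' @param train_frac training fraction of subjects (default 2/3).
#' @param k CV folds (default 5).
#' @param tune if `TRUE`, tune `mtry`/`ntree` over
#'   [default_tune_grid()]; otherwise use [default_hyperparams()].
#' @param ntree trees per forest when not tuning (default 500).
#' @param resample `"none"`, `"oversample"` or `"smote"` (training
#'   folds only).
#' @param nzv,corr_filter apply the near-zero-variance / correlation
#'   filter, fitted on each repeat's training rows and replayed on the
#'   test rows.
#' @param optimize_threshold select the decision threshold on the
#'   training data (default `TRUE`); otherwise use 0.5.
#' @param forward run forward view selection (default `TRUE`;
#'   meaningless under early integration).
#' @param importance compute permutation importance of the selected
#'   views (default `FALSE`).
#' @param n_perm permutations per feature for importance.
#' @param seed master seed for splitting and all fits.
#' @return an object of class `mv_experiment`: list with `metrics`
#'   (per-repeat data.frame: auc, sensitivity, specificity,
#'   threshold), `summary` (mean/sd of each metric), `selection`
#'   (per-repeat selected views and traces), `view_aucs` (per-repeat
#'   train/test AUC per view), `test_probs`/`test_labels`/`weights`
#'   (per-repeat per-view test probability matrices, test labels and
#'   full-ensemble weights, for audits such as exhaustive-subset
#'   checks), `importance` (aggregated table or `NULL`), `plan`, and
#'   the call parameters.
#' @export
run_experiment <- function(cohort, approach = 2,
                           integration = c("late", "early"),
                           n_repeats = 5, train_frac = 2 / 3, k = 5,
                           tune = FALSE, ntree = 500,
                           resample = c("none", "oversample", "smote"),
                           nzv = FALSE, corr_filter = FALSE,
                           optimize_threshold = TRUE, forward = TRUE,
                           importance = FALSE, n_perm = 100, seed = 1) {
  integration <- match.arg(integration)
  resample <- match.arg(resample)
  vw <- build_views(cohort, approach, seed = seed)
  if (integration == "early") {
    vw$tables <- list(early = concatenate_views(vw$tables))
    forward <- FALSE
  }
  plan <- grouped_stratified_split(cohort$meta, train_frac = train_frac,
                                   n_repeats = n_repeats, k = k,
                                   seed = seed)
  labels <- vw$unit_labels
  metrics <- NULL
  selection <- list()
  view_aucs <- list()
  imp_records <- list()
  probs_by_repeat <- list()
  labels_by_repeat <- list()
  weights_by_repeat <- list()

  for (r in seq_len(n_repeats)) {
    rep_plan <- plan$repeats[[r]]
    in_train <- vw$unit_subject[names(labels)] %in% rep_plan$train
    train_units <- names(labels)[in_train]
    test_units <- names(labels)[!in_train]
    unit_fold <- rep_plan$folds[vw$unit_subject[train_units]]
    names(unit_fold) <- train_units
    rep_seed <- seed + 1000L * r

    models <- list()
    test_probs <- list()
    for (vi in seq_along(vw$tables)) {
      vn <- names(vw$tables)[vi]
      v <- values(vw$tables[[vn]])
      tr_rows <- intersect(rownames(v), train_units)
      te_rows <- intersect(rownames(v), test_units)
      tr <- feature_table(v[tr_rows, , drop = FALSE],
                          vw$tables[[vn]]$modality, vn)
      te <- feature_table(v[te_rows, , drop = FALSE],
                          vw$tables[[vn]]$modality, vn)
      if (nzv) {
        f <- nzv_filter(tr)
        tr <- f$table; te <- keep_features(te, f$kept)
      }
      if (corr_filter) {
        f <- correlation_filter(tr)
        tr <- f$table; te <- keep_features(te, f$kept)
      }
      grid <- if (tune) default_tune_grid(ncol(values(tr)))
              else {
                hp <- default_hyperparams(ncol(values(tr)))
                hp$ntree <- as.integer(ntree)
                list(mtry = hp$mtry, ntree = hp$ntree)
              }
      vm <- tune_and_train(tr, labels[tr_rows], unit_fold,
                           mtry_grid = grid$mtry, ntree_grid = grid$ntree,
                           seed = rep_seed + vi, resample = resample)
      models[[vn]] <- vm
      models[[vn]]$test_table <- te
      test_probs[[vn]] <- predict(vm, te)
    }

    train_aucs <- vapply(models, function(m) m$train_auc, numeric(1))
    # a view that scores CV AUC 0 would zero out its weight's
    # denominator contribution; clamp to a small floor for safety
    weights <- compute_weights(pmax(train_aucs, 1e-6))

    prob_matrix <- matrix(NA_real_, length(test_units), length(models),
                          dimnames = list(test_units, names(models)))
    for (vn in names(models))
      prob_matrix[names(test_probs[[vn]]), vn] <- test_probs[[vn]]

    threshold <- if (optimize_threshold)
      select_threshold(lapply(models, function(m) m$oof_probs),
                       labels[train_units])
    else 0.5

    if (forward && length(models) > 1L) {
      fs <- forward_select(prob_matrix, labels[test_units], weights)
    } else {
      fs <- list(selected = names(models),
                 auc = auc(labels[test_units],
                           combine_probs(prob_matrix, weights)),
                 trace = NULL)
    }
    sel <- fs$selected
    w_sel <- weights[sel] / sum(weights[sel])
    combined <- combine_probs(prob_matrix[, sel, drop = FALSE], w_sel)
    ss <- sens_spec(labels[test_units], combined, threshold)
    metrics <- rbind(metrics, data.frame(
      split = r, auc = fs$auc, sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]], threshold = threshold))
    selection[[r]] <- fs
    probs_by_repeat[[r]] <- prob_matrix
    labels_by_repeat[[r]] <- labels[test_units]
    weights_by_repeat[[r]] <- weights
    view_aucs[[r]] <- data.frame(
      view = names(models), train_auc = unname(train_aucs),
      test_auc = vapply(names(models), function(vn)
        auc(labels[test_units],
            combine_probs(prob_matrix[, vn, drop = FALSE], 1)),
        numeric(1)),
      weight = unname(weights), selected = names(models) %in% sel,
      row.names = NULL)

    if (importance) {
      imp_records[[r]] <- permutation_importance(
        models[sel],
        lapply(models[sel], function(m) m$test_table),
        prob_matrix[, sel, drop = FALSE],
        labels[test_units], w_sel,
        n_perm = n_perm, seed = rep_seed + 77L)
    }
  }

  summary_df <- do.call(rbind, lapply(
    c("auc", "sensitivity", "specificity"),
    function(s) data.frame(statistic = s,
                           t(summarize_stat(metrics[[s]])))))
  structure(list(metrics = metrics, summary = summary_df,
                 selection = selection, view_aucs = view_aucs,
                 test_probs = probs_by_repeat,
                 test_labels = labels_by_repeat,
                 weights = weights_by_repeat,
                 importance = if (length(imp_records))
                   aggregate_importance(imp_records) else NULL,
                 importance_by_repeat = if (length(imp_records))
                   imp_records else NULL,
                 plan = plan,
                 params = list(approach = approach,
                               integration = integration, tune = tune,
                               resample = resample, seed = seed)),
            class = "mv_experiment")
}

#' @export
print.mv_experiment <- function(x, ...) {
  cat(sprintf("<mv_experiment> approach %d, %s integration, %d repeats\n",
              x$params$approach, x$params$integration, nrow(x$metrics)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report bundle
#'
#' `metrics.csv` (per-repeat rows plus mean/sd), `selection.csv`
#' (forward-selection traces) and, when computed, `importance.csv`.
#'
#' @param experiment an `mv_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- experiment$metrics
  utils::write.csv(m, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(experiment$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  traces <- do.call(rbind, lapply(seq_along(experiment$selection),
    function(r) {
      tr <- experiment$selection[[r]]$trace
      if (is.null(tr)) return(NULL)
      cbind(split = r, tr)
    }))
  if (!is.null(traces))
    utils::write.csv(traces, file.path(dir, "selection.csv"),
                     row.names = FALSE)
  if (!is.null(experiment$importance))
    utils::write.csv(experiment$importance,
                     file.path(dir, "importance.csv"), row.names = FALSE)
  invisible(dir)
}
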