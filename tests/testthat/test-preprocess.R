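test_that("aggregate_taxa sums member columns and preserves totals", {
  t1 <- make_ft(matrix(c(1, 2, 3, 4), 1, 4), "counts")
  map <- c(f01 = "gA", f02 = "gA", f03 = "gB", f04 = "gB")
  agg <- aggregate_taxa(t1, map)
  expect_equal(unname(values(agg)[1, ]), c(3, 7))
  expect_equal(feature_ids(agg), c("gA", "gB"))
  # identity mapping leaves the table unchanged
  ident <- setNames(paste0("f", sprintf("%02d", 1:4)), feature_ids(t1))
  expect_equal(values(aggregate_taxa(t1, ident)),
               values(t1), ignore_attr = TRUE)
  # random many-to-one map: column count = number of distinct groups
  set.seed(2)
  t2 <- random_ft(10, 173, "counts", counts = TRUE)
  map2 <- setNames(sample(paste0("g", 1:40), 173, replace = TRUE),
                   feature_ids(t2))
  agg2 <- aggregate_taxa(t2, map2)
  expect_equal(ncol(values(agg2)), length(unique(map2)))
  expect_equal(sum(values(agg2)), sum(values(t2)))
  expect_error(aggregate_taxa(t2, map2[-1]), "f01")
})

test_that("filter_low_total drops strictly-below-threshold features", {
  m <- cbind(f1 = c(0, 0), f2 = c(1, 1), f3 = c(1, 2), f4 = c(5, 5))
  rownames(m) <- c("s1", "s2")
  ft <- feature_table(m, "counts")
  out <- filter_low_total(ft, 3)
  expect_equal(feature_ids(out), c("f3", "f4"))  # totals 0,2 removed
  expect_equal(feature_ids(filter_low_total(out, 3)), c("f3", "f4"))
  # independent column-sum oracle on a random table
  t2 <- random_ft(20, 50, "counts", seed = 4, counts = TRUE)
  out2 <- filter_low_total(t2, 90)
  oracle <- feature_ids(t2)[colSums(values(t2)) >= 90]
  expect_identical(feature_ids(out2), oracle)
  # exclusion list is honored unconditionally
  expect_false("f4" %in% feature_ids(filter_low_total(ft, 3, exclude = "f4")))
  expect_warning(filter_low_total(ft, 1e6), "all features")
})

test_that("rclr centers log positives and turns zeros into missing", {
  ft <- make_ft(matrix(c(1, 10, 100, 0), 1, 4), "counts")
  out <- values(rclr(ft))
  expect_equal(unname(out[1, 1:3]), c(-log(10), 0, log(10)))
  expect_true(is.na(out[1, 4]))
  # identical positives map to zero
  expect_equal(unname(values(rclr(make_ft(matrix(5, 1, 3), "counts")))[1, ]),
               rep(0, 3))
  # properties: scale invariance and row-mean zero, over random tables
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rpois(60, 3), 6, 10)
    m[1, ] <- pmax(m[1, ], 1)  # guard the all-zero row error
    ft2 <- make_ft(m, "counts")
    r1 <- values(rclr(ft2))
    r2 <- values(rclr(make_ft(m * 17.3, "counts")))
    expect_equal(r1, r2, tolerance = 1e-12)
    expect_equal(unname(rowMeans(r1, na.rm = TRUE)), rep(0, 6),
                 tolerance = 1e-12)
  }
  expect_error(rclr(make_ft(rbind(c(0, 0), c(1, 2)), "counts")), "s01")
  expect_error(rclr(make_ft(matrix(-1, 2, 2), "counts")), "non-negative")
})

test_that("lod and missingness filters use the strict > 20% rule", {
  set.seed(8)
  m <- matrix(runif(10 * 6), 10, 6)
  m[1:2, 1] <- 0.01   # 2/10 below LOD: boundary, kept
  m[1:3, 2] <- 0.01   # 3/10: dropped
  ft <- make_ft(m, "npx")
  out <- lod_filter(ft, lod = 0.05)
  expect_true("f01" %in% feature_ids(out))
  expect_false("f02" %in% feature_ids(out))
  # brute-force survivor oracle with per-feature LODs
  lods <- setNames(runif(6, 0.2, 0.4), feature_ids(ft))
  vv <- values(ft)
  frac <- sapply(feature_ids(ft), function(f) mean(vv[, f] < lods[f]))
  expect_identical(feature_ids(lod_filter(ft, lods)),
                   feature_ids(ft)[frac <= 0.2])

  m2 <- matrix(rnorm(10 * 5), 10, 5)
  m2[1:2, 1] <- NA; m2[1:3, 2] <- NA
  ft2 <- make_ft(m2, "metabolite")
  out2 <- missingness_filter(ft2)
  expect_true("f01" %in% feature_ids(out2))
  expect_false("f02" %in% feature_ids(out2))
  expect_identical(feature_ids(missingness_filter(out2)), feature_ids(out2))
})

test_that("weight_normalize divides rows by positive weights", {
  ft <- make_ft(rbind(c(2, 4), c(3, 9)), "metabolite")
  out <- weight_normalize(ft, c(2, 3))
  expect_equal(unname(values(out)), rbind(c(1, 2), c(1, 3)))
  expect_equal(values(weight_normalize(ft, c(1, 1))), values(ft))
  # named weights are matched by sample id; element-wise oracle
  t2 <- random_ft(8, 5, "metabolite", seed = 9)
  w <- setNames(runif(8, 0.5, 2), rev(sample_ids(t2)))
  expect_equal(values(weight_normalize(t2, w)),
               values(t2) / w[sample_ids(t2)], ignore_attr = TRUE)
  expect_error(weight_normalize(ft, c(1, -1)), "positive")
  expect_error(weight_normalize(ft, c(a = 1)), "weight")
})

test_that("log2_transform transforms non-missing entries only", {
  ft <- make_ft(rbind(c(8, 1), c(2, NA)), "metabolite")
  out <- values(log2_transform(ft))
  expect_equal(unname(out[1, ]), c(3, 0))
  expect_equal(unname(out[2, 1]), 1)
  expect_true(is.na(out[2, 2]))
  expect_error(log2_transform(make_ft(rbind(c(0, 1)), "metabolite")),
               "non-positive")
})

test_that("qrilc_fit recovers the parameters of censored normals", {
  # N(0,1) censored below -1, n = 1000.  Simulation (200 replicates)
  # puts the per-fit sd of both estimates at ~0.034 with negligible
  # bias, so: average of 10 fits within +/-0.05, every fit within
  # +/-0.15 (~4.4 sigma).
  set.seed(21)
  fits <- t(replicate(10, {
    x <- rnorm(1000)
    lateRF:::qrilc_fit(x[x > -1], 1000)
  }))
  expect_lt(abs(mean(fits[, "mean"])), 0.05)
  expect_lt(abs(mean(fits[, "sd"]) - 1), 0.05)
  expect_true(all(abs(fits[, "mean"]) < 0.15))
  expect_true(all(abs(fits[, "sd"] - 1) < 0.15))
})

test_that("qrilc_impute draws below the observed minimum, reproducibly", {
  set.seed(22)
  m <- matrix(rnorm(40 * 8, mean = 5), 40, 8)
  for (j in 1:8) m[m[, j] < quantile(m[, j], 0.15), j] <- NA
  ft <- make_ft(m, "metabolite")
  out <- qrilc_impute(ft, seed = 5)
  expect_false(anyNA(values(out)))
  for (j in 1:8) {
    imp <- values(out)[is.na(m[, j]), j]
    expect_true(all(imp <= min(m[, j], na.rm = TRUE)))
  }
  # observed entries untouched; same seed reproduces; no-missing identity
  expect_equal(values(out)[!is.na(m)], m[!is.na(m)])
  expect_equal(values(qrilc_impute(ft, seed = 5)), values(out))
  expect_false(identical(values(qrilc_impute(ft, seed = 6)), values(out)))
  full <- make_ft(matrix(rnorm(20), 4, 5), "metabolite")
  expect_identical(values(qrilc_impute(full)), values(full))
  # <3 observed values: global fallback with warning
  m2 <- m; m2[3:40, 1] <- NA
  expect_warning(qrilc_impute(make_ft(m2, "metabolite"), seed = 1),
                 "global fit")
})

test_that("nzv_filter drops constant and 95/5 low-unique features", {
  set.seed(23)
  m <- cbind(const = rep(1, 100),
             incr = 1:100,
             bin95 = c(rep(0, 95), rep(1, 5)),
             noisy = rnorm(100))
  rownames(m) <- sprintf("s%03d", 1:100)
  out <- nzv_filter(feature_table(m, "clinical"))
  expect_identical(out$kept, c("incr", "noisy"))
  # replay on another table keeps the same columns
  replay <- keep_features(feature_table(m + 1, "clinical"), out$kept)
  expect_identical(feature_ids(replay), out$kept)
  # idempotent
  expect_identical(nzv_filter(out$table)$kept, out$kept)
})

test_that("correlation_filter leaves no pair above the cutoff", {
  set.seed(24)
  # two identical columns: exactly one survives
  m <- matrix(rnorm(40), 20, 2); m[, 2] <- m[, 1]
  out <- correlation_filter(make_ft(m), cutoff = 0.9)
  expect_equal(length(out$kept), 1L)
  # orthogonal-ish columns: identity
  m2 <- matrix(rnorm(200), 20, 10)
  expect_equal(length(correlation_filter(make_ft(m2), 0.99)$kept), 10L)
  # recheck oracle on a correlated random table
  base <- rnorm(30)
  m3 <- sapply(1:10, function(j) base + rnorm(30, sd = runif(1, 0.05, 2)))
  out3 <- correlation_filter(make_ft(m3), cutoff = 0.9)
  surv <- values(out3$table)
  if (ncol(surv) > 1) {
    cc <- abs(cor(surv)); diag(cc) <- 0
    expect_lte(max(cc), 0.9)
  }
  expect_identical(correlation_filter(out3$table, 0.9)$kept, out3$kept)
})

test_that("median imputation is fitted on training data only", {
  tr <- make_ft(rbind(c(1, NA), c(3, 10), c(5, 20)))
  imp <- fit_median_impute(tr)
  expect_equal(unname(imp$medians), c(3, 15))
  te <- make_ft(matrix(NA_real_, 1, 2))
  filled <- values(impute_median(te, imp))
  expect_equal(unname(filled[1, ]), c(3, 15))
})
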