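test_that("spec constructors validate their invariants", {
  expect_error(view_spec("v", "npx", 10, n_informative = 11), "n_informative")
  expect_error(view_spec("v", "npx", 10, effect_size = -1), "effect_size")
  expect_error(view_spec("v", "counts", 10, zero_frac = 1), "zero_frac")
  expect_error(view_spec("v", "metabolite", 10, censor_frac = -0.1),
               "censor_frac")
  expect_error(cohort_spec(n_subjects = 10, n_positive = 10), "n_positive")
  expect_error(cohort_spec(subject_corr = 1.2), "subject_corr")
})

test_that("generate_cohort emulates the cohort design", {
  co <- small_cohort(effect = 1, seed = 11, n_views = 3,
                     visits = c("baseline", "6M", "12M"))
  # one table per (view, visit)
  expect_length(co$tables, 9)
  expect_equal(nrow(co$manifest), 9)
  # 39 subjects, 15 positive
  outc <- subject_outcomes(co$meta)
  expect_length(outc, 39)
  expect_equal(sum(outc == "persistent"), 15)
  expect_equal(nrow(co$meta), 39 * 3)
  # same seed: byte-identical; different seed: different
  co2 <- small_cohort(effect = 1, seed = 11, n_views = 3,
                      visits = c("baseline", "6M", "12M"))
  expect_identical(lapply(co$tables, values), lapply(co2$tables, values))
  co3 <- small_cohort(effect = 1, seed = 12, n_views = 3,
                      visits = c("baseline", "6M", "12M"))
  expect_false(identical(values(co$tables[[2]]), values(co3$tables[[2]])))
})

test_that("counts views are compositional with the stated depth", {
  vs <- list(view_spec("b", "counts", 40, 5, 1, zero_frac = 0.3,
                       depth = 10000))
  co <- generate_cohort(cohort_spec(20, 8, visits = "v1", view_specs = vs,
                                    seed = 13))
  v <- values(co$tables[[1]])
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  expect_equal(unname(rowSums(v)), rep(10000, 20))
  expect_gt(mean(v == 0), 0.15)  # zero inflation present
})

test_that("metabolite censoring hits the requested missing fraction", {
  vs <- list(view_spec("m", "metabolite", 60, 0, 0, censor_frac = 0.2))
  co <- generate_cohort(cohort_spec(50, 20, visits = "v1", view_specs = vs,
                                    seed = 14))
  frac <- mean(is.na(values(co$tables[[1]])))
  expect_lt(abs(frac - 0.2), 0.02)
  # censoring is left-censoring: every missing value's feature minimum
  # observed is above nothing below it (observed values all exceed the
  # censor cut by construction) - check via per-feature ordering
  v <- values(co$tables[[1]])
  expect_true(all(colMeans(is.na(v)) <= 0.25))
})

test_that("informative features separate the classes (simulation oracle)", {
  vs <- list(view_spec("a", "npx", 30, n_informative = 5, effect_size = 1))
  co <- generate_cohort(cohort_spec(100, 40, visits = "v1",
                                    view_specs = vs, seed = 15))
  v <- values(co$tables[[1]])
  y <- subject_outcomes(co$meta)[sub("_v1$", "", rownames(v))]
  p_inf <- sapply(1:5, function(j)
    t.test(v[y == "persistent", j], v[y == "outgrown", j])$p.value)
  expect_true(all(p_inf < 0.01))
  p_noise <- sapply(6:30, function(j)
    t.test(v[y == "persistent", j], v[y == "outgrown", j])$p.value)
  expect_gt(mean(p_noise > 0.01), 0.7)
})

test_that("subject latent effects correlate across visits as configured", {
  vs <- list(view_spec("a", "npx", 40, 0, 0))
  mean_corr <- function(rho, seed) {
    co <- generate_cohort(cohort_spec(60, 20, visits = c("v1", "v2"),
                                      view_specs = vs, subject_corr = rho,
                                      seed = seed))
    v1 <- values(co$tables[["a_v1"]]); v2 <- values(co$tables[["a_v2"]])
    # correlate each subject's visit-1 and visit-2 deviation profiles
    d1 <- sweep(v1, 2, colMeans(v1)); d2 <- sweep(v2, 2, colMeans(v2))
    mean(sapply(1:60, function(i) cor(d1[i, ], d2[i, ])))
  }
  expect_gt(mean_corr(0.9, 16), mean_corr(0, 16) + 0.05)
})

test_that("a (view, visit, subject) cell can be dropped", {
  vs <- list(view_spec("a", "npx", 10, 0, 0), view_spec("b", "npx", 10, 0, 0))
  co <- generate_cohort(cohort_spec(10, 4, visits = c("v1", "v2"),
                                    view_specs = vs, seed = 17,
                                    drop_cell = list(view = "b", visit = "v2",
                                                     subject = "S003")))
  expect_equal(nrow(values(co$tables[["b_v2"]])), 9)
  expect_equal(nrow(values(co$tables[["a_v2"]])), 10)
  expect_false("S003_v2" %in% sample_ids(co$tables[["b_v2"]]))
})

test_that("cohorts round-trip through CSV", {
  co <- small_cohort(effect = 0, seed = 18, n_views = 1, p = 8,
                     visits = "v1", n_subjects = 8, n_positive = 3)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "meta.csv")))
  nm <- names(co$tables)[1]
  back <- read_feature_table(file.path(dir, paste0(nm, ".csv")),
                             modality = co$tables[[nm]]$modality, name = nm)
  expect_equal(values(back), values(co$tables[[nm]]))
})
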