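# a fitted single-view setup shared by the importance tests; the
# model is trained on half the rows and importance is measured on the
# held-out half (resubstitution would let the forest memorize noise
# features and mask the permutation effect)
imp_fixture <- function(n = 80, seed = 61, noise = 0.02) {
  d <- separable_xy(n = n, seed = seed, noise = noise)
  tr <- seq_len(n / 2)
  ft_tr <- make_ft(d$x[tr, ])
  folds <- setNames(rep(1:5, length.out = n / 2), rownames(d$x)[tr])
  vm <- tune_and_train(ft_tr, d$y[tr], folds, ntree_grid = 100, seed = seed)
  ft_te <- make_ft(d$x[-tr, ])
  p <- predict(vm, ft_te)
  pm <- matrix(p, ncol = 1, dimnames = list(names(p), "toy"))
  list(vm = vm, ft = ft_te, pm = pm,
       y = setNames(d$y[-tr], rownames(d$x)[-tr]))
}

test_that("permuting the label-copy feature destroys the AUC", {
  fx <- imp_fixture()
  imp <- permutation_importance(list(toy = fx$vm), list(toy = fx$ft),
                                fx$pm, fx$y, weights = 1, n_perm = 30,
                                seed = 2)
  # AUC 1 -> ~0.5: mean decrease ~0.5 (simulation-calibrated +/- 0.05)
  f01 <- imp[imp$feature == "f01", ]
  expect_equal(f01$mean_decrease, 0.5, tolerance = 0.12)
  expect_true(f01$important)
  expect_equal(imp$feature[1], "f01")  # sorted by decreasing mean
  expect_true(all(imp$sd_decrease >= 0))
  # fixed seed reproduces the whole table
  imp2 <- permutation_importance(list(toy = fx$vm), list(toy = fx$ft),
                                 fx$pm, fx$y, weights = 1, n_perm = 30,
                                 seed = 2)
  expect_identical(imp, imp2)
})

test_that("constant features have exactly zero decrease", {
  fx <- imp_fixture(seed = 62)
  v <- values(fx$ft)
  v[, "f02"] <- 3.14
  ft2 <- make_ft(v)
  imp <- permutation_importance(list(toy = fx$vm), list(toy = ft2),
                                fx$pm, fx$y, weights = 1, n_perm = 10,
                                seed = 3)
  expect_identical(imp$mean_decrease[imp$feature == "f02"], 0)
  expect_identical(imp$sd_decrease[imp$feature == "f02"], 0)
})

test_that("label-independent features have near-zero mean decrease", {
  fx <- imp_fixture(seed = 63)
  imp <- permutation_importance(list(toy = fx$vm), list(toy = fx$ft),
                                fx$pm, fx$y, weights = 1, n_perm = 100,
                                seed = 4)
  noise <- imp$mean_decrease[imp$feature != "f01"]
  expect_lt(abs(mean(noise)), 0.01)
  expect_error(permutation_importance(list(toy = fx$vm), list(toy = fx$ft),
                                      fx$pm, fx$y, 1, n_perm = 1),
               "n_perm")
})

test_that("only selected views are reported", {
  fx <- imp_fixture(seed = 64)
  imp <- permutation_importance(list(toy = fx$vm), list(toy = fx$ft),
                                fx$pm, fx$y, weights = 1, n_perm = 5,
                                seed = 5)
  expect_setequal(unique(imp$view), "toy")
  expect_setequal(imp$feature, fx$vm$features)
})

test_that("gini importance ranks the label copy first, never negative", {
  fx <- imp_fixture(seed = 65)
  gi <- gini_importance(fx$vm)
  expect_equal(names(gi)[1], "f01")
  expect_true(all(gi >= 0))
  expect_length(gini_importance(fx$vm, top_n = 3), 3)
  # pure noise: no feature dominates (3x median rule over 10 seeds)
  ratios <- sapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(sprintf("s%02d", 1:60), sprintf("f%02d", 1:10)))
    y <- rep(c(0, 1), 30)
    m <- random_forest(x, y, ntree = 100, seed = s)
    max(m$importance) / median(m$importance)
  })
  expect_lt(mean(ratios > 3), 0.3)
})

test_that("aggregate_importance applies the strict > 0.01 grand-mean rule", {
  rec <- function(f, d) data.frame(view = "v", feature = f,
                                   mean_decrease = d, sd_decrease = 0,
                                   important = d > 0.01,
                                   stringsAsFactors = FALSE)
  # boundary: per-repeat means [0.02, 0, 0, 0, 0.03] -> grand mean 0.01,
  # NOT important under the strict rule
  reps <- lapply(c(0.02, 0, 0, 0, 0.03), function(d)
    rbind(rec("fA", d), rec("fB", 0.02)))
  agg <- aggregate_importance(reps)
  expect_equal(agg$mean_decrease[agg$feature == "fA"], 0.01)
  expect_false(agg$important[agg$feature == "fA"])
  expect_true(agg$important[agg$feature == "fB"])
  # ordering matches an independent sort oracle
  set.seed(66)
  recs <- lapply(1:3, function(i) rec(sprintf("g%02d", 1:20), runif(20, 0, 0.05)))
  agg2 <- aggregate_importance(recs)
  grand <- rowMeans(sapply(recs, function(r)
    r$mean_decrease[match(agg2$feature, r$feature)]))
  expect_equal(agg2$mean_decrease, unname(grand))
  expect_false(is.unsorted(rev(agg2$mean_decrease)))
  # a feature absent from one repeat contributes zero there
  agg3 <- aggregate_importance(list(rec("fA", 0.03),
                                    rec("fB", 0.03)))
  expect_equal(agg3$mean_decrease[agg3$feature == "fA"], 0.015)
})
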