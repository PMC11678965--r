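# ML protocol: elbow geometry, forest ranking, AIC forward selection,
# cross-validated evaluation with undersampling and majority voting, and
# the no-leakage instrumentation check.

elbow_oracle <- function(v) {
  k <- length(v)
  d <- vapply(seq_len(k), function(i) {
    abs((v[k] - v[1]) * (i - 1) - (k - 1) * (v[i] - v[1])) /
      sqrt((v[k] - v[1])^2 + (k - 1)^2)
  }, numeric(1))
  which(d == max(d))[1]
}

make_informative <- function(n = 120, p = 10, n_inf = 1, delta = 2,
                             seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c(paste0("inf", seq_len(n_inf)),
                   paste0("noise", seq_len(p - n_inf)))
  y <- rep(c(0L, 1L), each = n / 2)
  X[, seq_len(n_inf)] <- X[, seq_len(n_inf)] + delta * y
  list(X = X, y = y)
}

test_that("find_elbow equals the brute-force distance scan", {
  expect_identical(find_elbow(c(10, 2, 1.5, 1.2, 1)),
                   elbow_oracle(c(10, 2, 1.5, 1.2, 1)))
  expect_identical(find_elbow(c(5, 4, 3, 2, 1)), 1L)
  expect_identical(find_elbow(rep(1, 6)), 1L)
  expect_error(find_elbow(c(2, 1)), ">= 3")
  set.seed(21)
  for (i in 1:100) {
    v <- sort(rexp(sample(3:40, 1)), decreasing = TRUE)
    expect_identical(find_elbow(v), elbow_oracle(v))
  }
})

test_that("rank_features puts the informative feature first", {
  hits <- vapply(1:20, function(s) {
    d <- make_informative(n = 200, p = 10, delta = 2, seed = 100 + s)
    ranked <- rank_features(d$X, d$y, seed = s, ntree = 200)
    ranked$feature[1] == "inf1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  d <- make_informative(seed = 1)
  expect_error(rank_features(d$X[, 1, drop = FALSE], d$y, seed = 1),
               ">= 2 features")
  expect_error(rank_features(d$X, rep(0L, nrow(d$X)), seed = 1),
               "degenerate")
})

test_that("duplicated features share importance roughly equally", {
  d <- make_informative(n = 200, p = 4, delta = 2, seed = 5)
  X <- cbind(d$X, inf1_copy = d$X[, "inf1"])
  ranked <- rank_features(X, d$y, seed = 9, ntree = 500)
  i1 <- ranked$importance[ranked$feature == "inf1"]
  i2 <- ranked$importance[ranked$feature == "inf1_copy"]
  expect_lt(max(i1, i2) / min(i1, i2), 2)
})

test_that("AIC selection keeps informative features and stays small", {
  sizes <- vapply(1:10, function(s) {
    d <- make_informative(n = 200, p = 22, n_inf = 2, delta = 2,
                          seed = 200 + s)
    set.seed(s)
    cand <- c("inf1", "inf2", paste0("noise", 1:10))
    length(select_by_aic(d$X, d$y, cand, seed = s, ntree = 150))
  }, numeric(1))
  expect_gte(mean(sizes <= 5), 0.9)
  d <- make_informative(seed = 3)
  expect_identical(select_by_aic(d$X, d$y, "inf1", seed = 1), "inf1")
  expect_error(select_by_aic(d$X, d$y, character(0)), "no candidates")
})

test_that("evaluate is deterministic, votes 5 times, and undersamples", {
  d <- make_informative(n = 60, p = 6, delta = 1.5, seed = 7)
  # unbalance the classes
  keep <- c(which(d$y == 0L), which(d$y == 1L)[1:18])
  X <- d$X[keep, ]; y <- d$y[keep]
  ev1 <- evaluate(X, y, seed = 3, ntree = 100)
  ev2 <- evaluate(X, y, seed = 3, ntree = 100)
  expect_identical(ev1$votes, ev2$votes)
  expect_identical(ev1$accuracy, ev2$accuracy)
  expect_identical(ncol(ev1$votes), 5L)
  expect_false(anyNA(ev1$votes))
  expect_identical(ev1$final,
                   as.integer(rowMeans(ev1$votes) >= 0.5))
  fc <- ev1$fold_class_counts
  expect_true(all(fc$n0 == fc$n1))
  expect_true(all(fc$n0 == fc$minority))
  expect_error(evaluate(d$X[1:12, ], rep(c(0L, 1L), c(8, 4)), seed = 1,
                        ntree = 50), "at least nfolds")
})

test_that("feature selection never sees the test fold (poison check)", {
  d <- make_informative(n = 80, p = 8, n_inf = 2, delta = 2.5, seed = 13)
  seed <- 17
  # reconstruct the replicate-1 folds exactly as evaluate() draws them
  set.seed(seed + 1)
  fold <- mobilitytrt:::stratified_folds(d$y, 5)
  te <- which(fold == 1)
  poison <- rnorm(nrow(d$X), 0, 0.1)
  poison[te] <- d$y[te] * 10 # perfectly separates the test fold only
  X <- cbind(d$X, poison = poison)
  ev <- evaluate(X, d$y, seed = seed, ntree = 150, nrep = 1)
  expect_false("poison" %in% ev$selected[["rep1_fold1"]])
})

test_that("label permutation drives accuracy to chance", {
  d <- make_informative(n = 40, p = 5, delta = 2, seed = 23)
  accs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    evaluate(d$X, sample(d$y), seed = s, ntree = 100,
             select = FALSE)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("duration-only model runs the same protocol on one predictor", {
  set.seed(31)
  dur <- c(rnorm(30, 10, 1), rnorm(30, 13, 1))
  y <- rep(c(0L, 1L), each = 30)
  ev <- duration_only_model(dur, y, seed = 2)
  expect_gt(ev$accuracy, 85)
  expect_identical(ncol(ev$votes), 5L)
  expect_error(duration_only_model(dur, rep(0L, 60), seed = 1),
               "both classes")
})

test_that("compare_trial_models reproduces the reference summary means", {
  acc <- reference_trial_accuracies()
  cmp <- compare_trial_models(acc)
  expect_equal(round(cmp$mean_diffs[["trial2"]], 1), -1.8)
  expect_equal(round(cmp$mean_diffs[["duration"]], 1), -7.0)
  expect_equal(round(cmp$mean_diffs[["both"]], 1), 0.3)

  allsame <- acc
  allsame$accuracy <- 80
  cmp0 <- compare_trial_models(allsame)
  expect_true(all(cmp0$table$diff_vs_trial1 == 0))
  expect_true(all(cmp0$mean_diffs == 0))

  expect_error(compare_trial_models(acc[-2, ]), "unmatched cell")
})

test_that("build_feature_matrix pivots, imputes and labels correctly", {
  p <- default_group_profiles()
  meas <- make_tug_measures(p$control, p$mild, n_per_group = 3, seed = 55)
  fm1 <- build_feature_matrix(meas, "TUG", "mild", feature_set = "trial1")
  expect_identical(sort(unique(fm1$y)), c(0L, 1L))
  expect_false(anyNA(fm1$X))
  fmb <- build_feature_matrix(meas, "TUG", "mild", feature_set = "both")
  expect_true(all(c("total_duration_t1", "total_duration_t2",
                    "total_duration_mean") %in% colnames(fmb$X)))
  t1 <- fmb$X[, "total_duration_t1"]; t2 <- fmb$X[, "total_duration_t2"]
  expect_equal(fmb$X[, "total_duration_mean"], (t1 + t2) / 2)
})
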