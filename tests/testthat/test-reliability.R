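# agreement statistics: ICC(A,1) against an independent ANOVA oracle,
# SEM/MDC/RC identities, Bland-Altman, classification thresholds.

# independent oracle: mean squares from stats::aov, ICC by the printed
# agreement formula
icc_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y)
  d <- data.frame(val = as.vector(y),
                  subj = factor(rep(seq_len(n), k)),
                  trial = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(val ~ subj + trial, data = d))[[1]][["Mean Sq"]]
  msp <- ms[1]; mst <- ms[2]; mse <- ms[3]
  (msp - mse) / (msp + (k - 1) * mse + (k / n) * (mst - mse))
}

test_that("icc_agreement matches the ANOVA oracle and handles edge cases", {
  m <- matrix(c(1, 2, 4, 3, 7, 9, 10, 8), ncol = 2, byrow = TRUE)
  res <- icc_agreement(m)
  expect_equal(res$icc, icc_oracle(m), tolerance = 1e-10)
  expect_equal(res$icc, 0.90566038, tolerance = 1e-7)

  perfect <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_identical(icc_agreement(perfect)$icc, 1)

  shift <- matrix(c(1, 2, 1, 2, 1, 2), ncol = 2, byrow = TRUE)
  expect_lte(icc_agreement(shift)$icc, 0)

  expect_error(icc_agreement(matrix(5, 3, 2)), "degenerate")
  expect_error(icc_agreement(matrix(1:4, 1, 4)), "n >= 2")
})

test_that("icc_agreement equals the oracle on random matrices", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    y <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 3)), n, 2) +
      rnorm(n) # participant effect
    expect_equal(icc_agreement(y)$icc, icc_oracle(y), tolerance = 1e-8)
  }
})

test_that("ICC is invariant to affine rescaling", {
  set.seed(7)
  for (i in 1:20) {
    y <- matrix(rnorm(20), 10, 2) + rnorm(10)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(icc_agreement(a * y + b)$icc, icc_agreement(y)$icc,
                 tolerance = 1e-10)
  }
})

test_that("larger participant variance raises the ICC", {
  mean_icc <- vapply(c(0.5, 1, 2), function(sp) {
    iccs <- vapply(1:20, function(s) {
      vc <- variance_components(sigma_p = sp, sigma_t = 0.2, sigma_e = 1)
      icc_agreement(trial_matrix(
        simulate_measure_table(vc, n = 50, k = 2, seed = 5000 + s)))$icc
    }, numeric(1))
    mean(iccs)
  }, numeric(1))
  expect_true(all(diff(mean_icc) > 0))
})

test_that("SEM and MDC follow their formulas", {
  expect_equal(sem(2, 0.75), 1)
  expect_equal(sem(3.7, 1), 0)
  expect_equal(sem(3, 0.19), 2.7, tolerance = 1e-10)
  expect_error(sem(1, 1.2), "<= 1")
  expect_equal(mdc(1), 2.7719, tolerance = 1e-4)
  expect_equal(mdc(0), 0)
  set.seed(1)
  s <- runif(20, 0.01, 10)
  expect_equal(mdc(s) / s, rep(1.96 * sqrt(2), 20))
})

test_that("relative change and its group summaries", {
  expect_equal(relative_change(10, 9), -0.1)
  expect_equal(relative_change(7.3, 7.3), 0)
  expect_equal(relative_change(8, 10), 0.25)
  expect_error(relative_change(0, 1), "> 0")

  s <- group_rc_summary(c(-0.1, -0.2, -0.3))
  expect_equal(s$median_rc, -0.2)
  expect_equal(s$median_abs_rc, 0.2)
  expect_equal(group_rc_summary(0.17)$median_rc, 0.17)
  sm <- group_rc_summary(c(-0.4, 0.1, 0.2))
  expect_equal(sm$median_rc, 0.1)
  expect_equal(sm$median_abs_rc, 0.2)
})

test_that("Bland-Altman summary matches its definitions", {
  ident <- cbind(1:5, 1:5)
  ba0 <- bland_altman(ident)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)

  set.seed(8)
  y1 <- rnorm(500, 10, 2)
  y <- cbind(y1, y1 + rnorm(500, 0.5, 1))
  ba <- bland_altman(y)
  expect_equal(ba$bias, mean(y[, 2] - y[, 1]))
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  expect_gt(ba$prop_inside, 0.93)
  expect_lt(ba$prop_inside, 0.97)
  expect_error(bland_altman(y[1:2, ]), "n >= 3")
  expect_error(bland_altman(matrix(1:9, 3, 3)), "2 trials")
})

test_that("ICC labels use the published thresholds", {
  expect_identical(classify_icc(0.3), "poor")
  expect_identical(classify_icc(0.8), "good")
  expect_identical(classify_icc(0.95), "excellent")
  expect_identical(classify_icc(c(0.5, 0.75, 0.90, 0.901)),
                   c("moderate", "good", "good", "excellent"))
  expect_identical(classify_icc(-0.4), "poor")
  expect_error(classify_icc(1.2), "<= 1")
})

test_that("trial_matrix drops incomplete participants with a count", {
  df <- data.frame(
    participant_id = rep(c("a", "b", "c", "d"), 2),
    trial = rep(1:2, each = 4),
    value = c(1, 2, 3, 4, 1.1, NA, 3.2, 4.1))
  tm <- trial_matrix(df)
  expect_identical(nrow(tm$values), 3L)
  expect_identical(tm$n_dropped, 1L)
})

test_that("reliability_table produces the full schema per cell", {
  vc <- variance_components(mu = 12, sigma_p = 2, sigma_t = 0.1,
                            sigma_e = 0.5)
  meas <- simulate_measure_table(vc, n = 30, k = 2, seed = 3,
                                 measure_name = "total_duration")
  meas$group <- "control"; meas$task <- "TUG"
  rel <- reliability_table(meas)
  expect_identical(nrow(rel), 1L)
  expect_true(all(c("icc", "ci_low", "ci_high", "label", "sem", "mdc",
                    "median_rc", "median_abs_rc", "ba_bias", "ba_loa_low",
                    "ba_loa_high", "n_used") %in% names(rel)))
  expect_equal(rel$mdc, rel$sem * 1.96 * sqrt(2))
  expect_lte(rel$ci_low, rel$icc)
  expect_gte(rel$ci_high, rel$icc)
  expect_identical(rel$n_used, 30L)
})
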