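test_that("dose encodings behave as documented", {
  expect_equal(encode_dose(c(0, 0.5, 5, 50)), c(0, 1, 2, 3))
  expect_equal(encode_dose(c(0, 0.5)), c(0, 1))
  expect_equal(encode_dose(c(50, 0, 5, 0.5)), c(3, 0, 2, 1))
  expect_equal(encode_dose(c(0, 0.5, 5), "raw"), c(0, 0.5, 5))
  expect_equal(encode_dose(c(0, 0.5, 5, 50), "log10", delta = 0.05),
               log10(c(0, 0.5, 5, 50) + 0.05))
  expect_error(encode_dose(c(-1, 0)), "non-negative")
})

test_that("pearson_r matches a from-definition computation", {
  x <- c(0, 1, 2, 3)
  y <- c(1, 2, 2, 4)
  # oracle: direct covariance / variance computation + t transform
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_def <- r_def * sqrt((4 - 2) / (1 - r_def^2))
  p_def <- 2 * pt(-abs(t_def), 4 - 2)

  got <- pearson_r(x, y)
  expect_equal(got$r, r_def, tolerance = 1e-12)
  expect_equal(got$p, p_def, tolerance = 1e-12)

  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
})

test_that("wald_slope_test matches the closed-form OLS t statistic", {
  x <- c(0, 1, 2, 3)
  y <- c(0.2, 1.1, 1.8, 3.2)
  sxx <- sum((x - mean(x))^2)
  slope_def <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - slope_def * mean(x)) - slope_def * x
  se_def <- sqrt(sum(resid^2) / (4 - 2) / sxx)
  p_def <- 2 * pt(-abs(slope_def / se_def), 4 - 2)

  got <- wald_slope_test(x, y)
  expect_equal(got$slope, slope_def, tolerance = 1e-12)
  expect_equal(got$se, se_def, tolerance = 1e-12)
  expect_equal(got$p, p_def, tolerance = 1e-12)

  flat <- wald_slope_test(x, rep(2, 4))
  expect_equal(flat$slope, 0)
  expect_gt(flat$p, 0.99)
  exact <- wald_slope_test(x, 3 * x)
  expect_equal(exact$p, 0)
})

test_that("vectorised dose association agrees with the scalar tests", {
  set.seed(42)
  x <- rep(0:3, each = 3)
  y <- matrix(rnorm(12 * 8), 12, 8)
  y[, 1] <- 5  # constant column convention: r = 0, p = 1
  fast <- catechoflux:::dose_association(x, y)
  expect_equal(fast$r[1], 0)
  expect_equal(fast$r_p[1], 1)
  for (j in 2:8) {
    expect_equal(fast$r[j], pearson_r(x, y[, j])$r, tolerance = 1e-10)
    expect_equal(fast$r_p[j], pearson_r(x, y[, j])$p, tolerance = 1e-10)
    expect_equal(fast$slope[j], wald_slope_test(x, y[, j])$slope,
                 tolerance = 1e-10)
    expect_equal(fast$wald_p[j], wald_slope_test(x, y[, j])$p,
                 tolerance = 1e-10)
  }
})

test_that("mann_whitney_u gives exact small-sample p-values and symmetries", {
  # fully separated 3 vs 3: U = 0, exact one-sided p = 1/20
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 1 / 20)

  # identical ranks: U = n1 n2 / 2
  sym <- mann_whitney_u(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(sym$U + mann_whitney_u(c(2, 4, 6, 8), c(1, 3, 5, 7))$U,
               4 * 4)

  a <- c(1.2, 5.3, 2.2, 8.0)
  b <- c(0.4, 2.9, 7.7)
  expect_equal(mann_whitney_u(a, b)$U, 4 * 3 - mann_whitney_u(b, a)$U)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("an exact planted dose ramp is selected by all three gates", {
  # one responder with lfc (0,1,2,3) across ordinal doses at T24, zero noise
  doses <- c(0, 0.5, 5, 50)
  tbl <- sample_table(tibble::tibble(
    sample_id = paste0("s", 1:4), dose = doses, time = 24,
    donor = "don1", batch = "don1",
    RESP = 100 * 2^c(0, 1, 2, 3), FLAT = 50
  ))
  fc <- log2_fold_change(tbl, pseudo = 0)
  res <- select_responders(fc, tbl, times = 24, pseudo = 0)
  expect_equal(selected_features(res), "RESP")
  row <- res[res$feature == "RESP", ]
  expect_equal(row$max_abs_lfc, 3)
  expect_equal(row$r, 1)
  expect_lt(row$wald_p, 0.05)
  expect_false(res$selected[res$feature == "FLAT"][1])
})

test_that("selection recovers planted responders on simulated data", {
  sim <- simulate_feature_table(simulation_config(n_features = 200,
                                                  n_responders = 20,
                                                  seed = 7))
  norm <- quantile_normalize(sim$samples)
  fc <- log2_fold_change(norm)
  res <- select_responders(fc, norm)
  perf <- selection_performance(selected_features(res), sim$truth)
  expect_gte(perf$sensitivity, 0.9)
  expect_gte(perf$precision, 0.9)
})

test_that("selection is monotone in its thresholds", {
  sim <- simulate_feature_table(simulation_config(n_features = 80,
                                                  n_responders = 12,
                                                  seed = 13))
  norm <- quantile_normalize(sim$samples)
  fc <- log2_fold_change(norm)
  strict <- selected_features(select_responders(fc, norm,
                                                lfc_threshold = 1,
                                                r_threshold = 0.9))
  loose <- selected_features(select_responders(fc, norm,
                                               lfc_threshold = 0.5,
                                               r_threshold = 0.8))
  expect_true(all(strict %in% loose))
})

test_that("null data yields only chance-level selections", {
  fp <- vapply(1:5, function(s) {
    sim <- simulate_feature_table(simulation_config(n_features = 150,
                                                    n_responders = 0,
                                                    seed = 100 + s))
    norm <- quantile_normalize(sim$samples)
    fc <- log2_fold_change(norm)
    length(selected_features(select_responders(fc, norm))) / 150
  }, numeric(1))
  expect_lt(mean(fp), 0.05)
})
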