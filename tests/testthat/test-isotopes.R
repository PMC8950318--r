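test_that("correction matrix has the stated closed form and column sums", {
  expect_equal(correction_matrix(2, 0), diag(3))
  expect_equal(correction_matrix(1, 0.0107),
               matrix(c(0.9893, 0.0107, 0, 1), 2, 2))
  for (n in c(2, 4, 6)) {
    for (a in c(0.0107, 0.00364, 0.2)) {
      cm <- correction_matrix(n, a)
      expect_equal(unname(colSums(cm)), rep(1, n + 1), tolerance = 1e-12)
      expect_true(all(cm[upper.tri(cm)] == 0))
    }
  }
  expect_error(correction_matrix(2, 1), "abundance")
})

test_that("natural-abundance correction inverts the forward convolution", {
  a <- 0.0107
  x <- c(0.6, 0, 0.4, 0)
  measured <- as.vector(correction_matrix(3, a) %*% x)
  expect_equal(correct_natural_abundance(measured, a), x,
               tolerance = 1e-9)

  # the pure natural-abundance pattern corrects to fully unlabeled
  nat <- as.vector(correction_matrix(3, a) %*% c(1, 0, 0, 0))
  expect_equal(correct_natural_abundance(nat, a), c(1, 0, 0, 0),
               tolerance = 1e-9)

  # a = 0 passes through
  expect_equal(correct_natural_abundance(x, 0), x)
})

test_that("convolve-correct round trip holds on randomized vectors", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    x <- runif(n + 1)
    x <- x / sum(x)
    a <- runif(1, 0, 0.05)
    measured <- as.vector(correction_matrix(n, a) %*% x)
    got <- correct_natural_abundance(measured, a)
    expect_lt(max(abs(got - x)), 1e-8)
    # output is a valid isotopologue vector
    expect_true(all(got >= 0))
    expect_equal(sum(got), 1, tolerance = 1e-9)
    # and mean enrichment is preserved by the round trip
    expect_equal(mean_enrichment(got), mean_enrichment(x),
                 tolerance = 1e-8)
  }
})

test_that("mean enrichment is the label-weighted average", {
  expect_equal(mean_enrichment(c(1, 0, 0)), 0)
  expect_equal(mean_enrichment(c(0, 0, 0, 1)), 1)
  expect_equal(mean_enrichment(c(0.5, 0.25, 0.25)), 0.375)
  expect_error(mean_enrichment(c(0.5, 0.4)), "sum to 1")
})

test_that("theoretical maxima reproduce the tracer worked values", {
  lac <- theoretical_max_enrichment(model_lactate_from_glucose12(),
                                    tracer_design_glucose12())
  expect_equal(lac, 0.5 * 0.99 * 1 / 3)
  expect_equal(round(100 * lac, 1), 16.5)

  glu <- theoretical_max_enrichment(model_glutamate_from_glucose12(),
                                    tracer_design_glucose12())
  expect_equal(glu, 0.25)

  # saturation
  sat <- theoretical_max_enrichment(
    atom_transfer_model("sat", 3, 3),
    tracer_design("C", tracer_fraction = 1, purity = 1))
  expect_equal(sat, 1)

  # purity can only shrink the maximum, equality iff purity = 1
  d99 <- tracer_design_glucose12(purity = 0.99)
  d100 <- tracer_design_glucose12(purity = 1)
  m <- model_lactate_from_glucose12()
  expect_lt(theoretical_max_enrichment(m, d99, apply_purity = TRUE),
            theoretical_max_enrichment(m, d99, apply_purity = FALSE))
  expect_equal(theoretical_max_enrichment(m, d100, apply_purity = TRUE),
               theoretical_max_enrichment(m, d100, apply_purity = FALSE))
})

test_that("fractional contributions reproduce the worked numbers", {
  expect_equal(fractional_contribution(0, 0.25), 0)
  expect_equal(fractional_contribution(0.25, 0.25), 1)
  expect_equal(100 * fractional_contribution(0.0448, 0.25), 17.92)
  expect_warning(clipped <- fractional_contribution(0.3, 0.25), "clipped")
  expect_equal(clipped, 1)
  expect_error(fractional_contribution(0.1, 0), "e_max")
})

test_that("pre-existing-pool correction solves the media-lactate case", {
  e_max <- theoretical_max_enrichment(model_lactate_from_glucose12(),
                                      tracer_design_glucose12())
  # oracle: solve c * (1 - phi) * e_max = e_obs for phi at c = 0.867
  phi <- 1 - 0.135 / (0.867 * e_max)
  expect_equal(contribution_with_preexisting_pool(0.135, phi, e_max),
               0.867, tolerance = 1e-9)
  expect_equal(phi, 0.0566, tolerance = 0.01)

  # phi = 0 reduces to the plain contribution
  expect_equal(contribution_with_preexisting_pool(0.1, 0, 0.165),
               fractional_contribution(0.1, 0.165))
  # strictly increasing in phi
  vals <- vapply(c(0, 0.2, 0.4, 0.6),
                 function(p) contribution_with_preexisting_pool(0.05, p,
                                                                0.165),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(contribution_with_preexisting_pool(0.1, 1, 0.165), "phi")
})

test_that("PPP split-ratio estimators follow their formulas", {
  expect_equal(ppp_fraction(0, 0.5), 0)
  expect_equal(ppp_fraction(0, 0.5, "simple"), 0)
  expect_equal(ppp_fraction(0.2, 0.2), 0.25)
  expect_equal(ppp_fraction(0.2, 0.2, "simple"), 0.5)
  # small-ratio limit: lee ~ (m1/m2)/3
  expect_equal(ppp_fraction(0.01, 1), 0.01 / 3, tolerance = 0.005)
  both <- ppp_fraction(0.03, 0.5, "all")
  expect_equal(both$ppp_fraction[both$estimator == "lee"],
               (0.03 / 0.5) / (3 + 0.03 / 0.5))
  expect_error(ppp_fraction(0.1, 0), "lee")
  expect_error(ppp_fraction(0, 0), "not both")
})

test_that("enrichment_summary chains the full computation", {
  des <- tracer_design_glucose12()
  v <- simulate_isotopologues(des, model_lactate_from_glucose12(), 0.6)
  out <- enrichment_summary(v, des, model_lactate_from_glucose12())
  expect_equal(out$contribution, 0.6, tolerance = 1e-9)
  expect_equal(out$theoretical_max, 0.165)
  expect_error(enrichment_summary(c(0.5, 0.5), des,
                                  model_lactate_from_glucose12()),
               "product_atoms")
})
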