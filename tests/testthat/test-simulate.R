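test_that("feature-table simulation is deterministic and matches its design", {
  cfg <- simulation_config(n_features = 40, n_responders = 8, seed = 11)
  sim1 <- simulate_feature_table(cfg)
  sim2 <- simulate_feature_table(cfg)
  expect_identical(sim1, sim2)

  expect_equal(nrow(sim1$samples),
               length(cfg$doses) * length(cfg$times) * cfg$n_donors)
  expect_length(feature_cols(sim1$samples), 40)
  expect_true(all(sim1$truth$responder_ids %in% feature_cols(sim1$samples)))
  expect_length(sim1$truth$responder_ids, 8)
})

test_that("zero-noise intensities equal baseline times 2^planted_lfc exactly", {
  cfg <- simulation_config(n_features = 20, n_responders = 6,
                           noise_sd = 0, donor_sd = 0, seed = 2)
  sim <- simulate_feature_table(cfg)
  m <- intensity_matrix(sim$samples)
  meta <- sim$samples[c("sample_id", "dose", "time", "donor")]

  lfc_of <- function(f, d, t) {
    rows <- sim$truth$planted_lfc
    hit <- rows$feature == f & rows$dose == d & rows$time == t
    if (any(hit)) rows$lfc[hit] else 0
  }
  for (f in c(sim$truth$responder_ids[1:2], "F0020")) {
    for (i in seq_len(nrow(meta))) {
      ctrl <- meta$sample_id[meta$dose == 0 & meta$time == meta$time[i] &
                               meta$donor == meta$donor[i]]
      ratio <- m[meta$sample_id[i], f] / m[ctrl, f]
      expect_equal(unname(ratio),
                   2^lfc_of(f, meta$dose[i], meta$time[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("planted responder |lfc| is monotone in ordinal dose at active times", {
  cfg <- simulation_config(n_features = 30, n_responders = 14, seed = 5)
  sim <- simulate_feature_table(cfg)
  by_ft <- split(sim$truth$planted_lfc,
                 list(sim$truth$planted_lfc$feature,
                      sim$truth$planted_lfc$time))
  for (grp in by_ft) {
    grp <- grp[order(match(grp$dose, cfg$doses)), ]
    expect_true(all(diff(abs(grp$lfc)) >= -1e-12))
  }
})

test_that("null simulation has no planted effects", {
  sim <- simulate_feature_table(simulation_config(n_features = 15,
                                                  n_responders = 0,
                                                  seed = 3))
  expect_length(sim$truth$responder_ids, 0)
  expect_equal(nrow(sim$truth$planted_lfc), 0)
})

test_that("config validation rejects broken designs", {
  expect_error(simulation_config(doses = c(0.5, 5)), "include 0")
  expect_error(simulation_config(n_features = 0), "n_features")
  expect_error(simulation_config(n_features = 5, n_responders = 9),
               "n_responders")
  expect_error(simulation_config(noise_sd = -1), "sigmas")
})

test_that("archetype profiles carry their planted shapes and apportionment", {
  ap <- simulate_archetype_profiles(n_features = 40, noise_sd = 0, seed = 1)
  expect_equal(dim(ap$profiles), c(40, 6))
  counts <- table(ap$archetype_of)
  expect_equal(as.integer(counts[c("down_rebound", "up_both")]),
               c(12L, 10L))
  # zero-noise early_up profile: active ramp at t4 columns, zeros at t24
  f <- names(ap$archetype_of)[ap$archetype_of == "early_up"][1]
  expect_equal(unname(ap$profiles[f, ]), c(2 / 3, 4 / 3, 2, 0, 0, 0))
})

test_that("simulated isotopologues honour the enrichment contract", {
  des <- tracer_design_glucose12()
  mod <- model_lactate_from_glucose12()

  # unlabeled, no natural abundance
  des0 <- tracer_design("C", natural_abundance = 0)
  v0 <- simulate_isotopologues(des0, mod, contribution = 0, noise_sd = 0)
  expect_equal(v0, c(1, 0, 0, 0))

  # saturation: pure tracer, pure isotope
  des1 <- tracer_design("C", natural_abundance = 0, tracer_fraction = 1,
                        purity = 1)
  v1 <- simulate_isotopologues(des1, mod, contribution = 1, noise_sd = 0)
  expect_equal(mean_enrichment(v1),
               mod$expected_labeled_atoms / mod$product_atoms)

  # lactate preset at contribution 0.5: corrected enrichment = 8.25%
  v <- simulate_isotopologues(des, mod, contribution = 0.5, noise_sd = 0)
  corrected <- correct_natural_abundance(v, des$natural_abundance)
  expect_equal(mean_enrichment(corrected), 0.5 * 0.165, tolerance = 1e-9)

  expect_error(simulate_isotopologues(des, mod, contribution = 1.5),
               "contribution")
})

test_that("seahorse simulation produces the stated cycle structure", {
  run <- flat_seahorse(n_wells = 2)
  expect_equal(nrow(run), 2 * 15)
  expect_equal(as.integer(table(run$phase)[c("basal", "oligomycin",
                                             "fccp", "rotaa")]),
               c(12L, 6L, 6L, 6L))
  # phases appear in order within each well
  ord <- run |> dplyr::filter(well == "w01") |> dplyr::arrange(cycle)
  expect_equal(rle(ord$phase)$values,
               c("basal", "oligomycin", "fccp", "rotaa"))

  run_a <- simulate_seahorse(tibble::tibble(condition = "c",
                                            basal_ocr = 100,
                                            basal_ecar = 10),
                             noise_sd = 0.2, seed = 9)
  run_b <- simulate_seahorse(tibble::tibble(condition = "c",
                                            basal_ocr = 100,
                                            basal_ecar = 10),
                             noise_sd = 0.2, seed = 9)
  expect_identical(run_a, run_b)
  expect_error(simulate_seahorse(tibble::tibble(condition = "c",
                                                basal_ocr = 100,
                                                basal_ecar = 10),
                                 n_wells = 0), "n_wells")
})

test_that("media time course integrates rates and clips negatives", {
  # constant rates of zero: constant concentrations
  tc0 <- simulate_media_timecourse(c(glc = 0), c(glc = 5), cells0 = 1e6,
                                   times = c(0, 4, 24))
  expect_equal(unique(tc0$concentration), 5)

  # closed form: dC = r * N * T / (1e6 * V)
  tc <- simulate_media_timecourse(c(lac = 0.1), c(lac = 1), cells0 = 2e6,
                                  growth = 0, volume_ml = 2,
                                  times = c(0, 24))
  expect_equal(unname(diff(tc$concentration)), 0.1 * 2 * 24 / 2,
               tolerance = 1e-12)

  expect_warning(
    simulate_media_timecourse(c(glc = -1), c(glc = 0.1), cells0 = 1e7,
                              times = c(0, 24)),
    "clipped")
  expect_error(simulate_media_timecourse(c(glc = 0), c(glc = 1),
                                         cells0 = 1e6, times = numeric(0)),
               "non-empty")
})
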