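#' Temporal response archetypes
#'
#' Dose-responding features in catecholamine-stimulated endothelial cells
#' fall into seven temporal patterns relative to unstimulated controls:
#' a drop at 4 h that rebounds by 24 h, an increase at both times, an
#' increase then decrease, a decrease then increase, an early-only increase,
#' a late-only decrease and a late-only increase. Each archetype is encoded
#' as a pair of signed multipliers applied to the planted effect at the
#' early (0 < t <= 4 h) and late (t > 4 h) time points.
#'
#' @return A tibble with columns `archetype`, `early` and `late`.
#' @export
response_archetypes <- function() {
  tibble(
    archetype = c("down_rebound", "up_both", "up_then_down", "down_then_up",
                  "early_up", "late_down", "late_up"),
    early = c(-1, 1, 1, -1, 1, 0, 0),
    late  = c( 0, 1, -1, 1, 0, -1, 1)
  )
}

#' Simulation configuration
#'
#' Describes the experimental design emulated by [simulate_feature_table()]:
#' an equimolar catecholamine dose series crossed with pretreatment times and
#' primary-cell donors, with a planted minority of dose-responding features.
#'
#' Planted log2 fold changes are log-linear in ordinal dose index (doses are
#' decade-spaced with a zero, so the ordinal encoding 0,1,2,... is used;
#' see [encode_dose()]): a responder's planted log2 FC at dose rank `d` of
#' `D` and time `t` is `effect_size * (d/D) * m(t)` where `m` is the
#' archetype multiplier of [response_archetypes()]. Intensities are the
#' feature baseline times `2^lfc`, times a per-donor multiplicative offset
#' shared across features (the donor/batch effect), times lognormal
#' measurement noise.
#'
#' @param doses Dose series in µM; must contain 0 (the fold-change
#'   reference).
#' @param times Sampling times in hours; must contain 0 and at least one
#'   treated time.
#' @param n_donors Number of donors (one batch per donor).
#' @param n_features Number of metabolic features.
#' @param n_responders Number of planted dose-responders
#'   (`<= n_features`).
#' @param archetype_weights Proportions over the seven archetypes, in the
#'   order of [response_archetypes()]; normalised internally. The default
#'   makes the down-rebound cluster largest and the up-at-both-times cluster
#'   second, with smaller remaining clusters.
#' @param effect_size Maximum absolute planted log2 fold change, reached at
#'   the highest dose at the archetype's active time.
#' @param noise_sd Lognormal sigma (natural-log scale) of multiplicative
#'   measurement noise per intensity.
#' @param donor_sd Lognormal sigma of the per-donor multiplicative offset.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of per-feature
#'   baseline intensities.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(doses = c(0, 0.5, 5, 50),
                              times = c(0, 4, 24),
                              n_donors = 3,
                              n_features = 500,
                              n_responders = 40,
                              archetype_weights = c(0.30, 0.25, 0.10, 0.10,
                                                    0.10, 0.075, 0.075),
                              effect_size = 2,
                              noise_sd = 0.1,
                              donor_sd = 0.2,
                              baseline_meanlog = log(1e4),
                              baseline_sdlog = 1,
                              seed = 1L) {
  if (length(doses) < 2 || !0 %in% doses) {
    abort("doses must include 0 (the fold-change reference) and a treated dose")
  }
  if (!0 %in% times || !any(times > 0)) {
    abort("times must include 0 and at least one treated time")
  }
  if (n_features < 1) abort("n_features must be positive")
  if (n_responders < 0 || n_responders > n_features) {
    abort("n_responders must lie in [0, n_features]")
  }
  if (length(archetype_weights) != 7 || any(archetype_weights < 0)) {
    abort("archetype_weights must be 7 non-negative proportions")
  }
  if (noise_sd < 0 || donor_sd < 0) abort("sigmas must be >= 0")
  structure(
    list(doses = sort(unique(doses)), times = sort(unique(times)),
         n_donors = as.integer(n_donors),
         n_features = as.integer(n_features),
         n_responders = as.integer(n_responders),
         archetype_weights = archetype_weights / sum(archetype_weights),
         effect_size = effect_size, noise_sd = noise_sd,
         donor_sd = donor_sd, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Largest-remainder apportionment of n responders over the archetype weights,
# so counts are deterministic and sum to n.
apportion_archetypes <- function(n, weights) {
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

archetype_multiplier <- function(archetype, time) {
  arch <- response_archetypes()
  early <- setNames(arch$early, arch$archetype)[archetype]
  late <- setNames(arch$late, arch$archetype)[archetype]
  ifelse(time <= 0, 0, ifelse(time <= 4, early, late))
}

#' Simulate a sample-by-feature intensity table with known ground truth
#'
#' Generates one sample per (dose, time, donor) cell of the design in
#' `config`, with `n_responders` features planted as dose-responders (see
#' [simulation_config()] for the intensity model) and the rest flat up to
#' noise.
#'
#' @param config A [simulation_config()].
#' @return A list with class `cf_simulation`:
#' \describe{
#'   \item{samples}{a [sample_table()] tibble;}
#'   \item{truth}{a list with `responder_ids` (character), `archetype_of`
#'     (named character, responders only) and `planted_lfc` (tibble
#'     `feature`, `dose`, `time`, `lfc`; non-responders have planted log2 FC
#'     0 everywhere and are omitted).}
#' }
#' @examples
#' sim <- simulate_feature_table(simulation_config(n_features = 50,
#'                                                 n_responders = 5))
#' dim(sim$samples)
#' head(sim$truth$responder_ids)
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  feats <- sprintf("F%04d", seq_len(config$n_features))
  donors <- sprintf("don%d", seq_len(config$n_donors))
  design <- tidyr::expand_grid(dose = config$doses, time = config$times,
                               donor = donors)
  design$sample_id <- sprintf("D%s_T%s_%s", design$dose, design$time,
                              design$donor)
  design$batch <- design$donor

  # ground truth: first n_responders features, archetypes apportioned by
  # weight so cluster sizes are deterministic
  responders <- head(feats, config$n_responders)
  counts <- apportion_archetypes(config$n_responders,
                                 config$archetype_weights)
  archetype_of <- setNames(rep(response_archetypes()$archetype, counts),
                           responders)

  dose_rank <- match(design$dose, config$doses) - 1
  max_rank <- length(config$doses) - 1

  planted_lfc <- tidyr::expand_grid(feature = responders,
                                    dose = config$doses,
                                    time = config$times)
  planted_lfc$lfc <- config$effect_size *
    (match(planted_lfc$dose, config$doses) - 1) / max_rank *
    archetype_multiplier(archetype_of[planted_lfc$feature], planted_lfc$time)

  baseline <- rlnorm(config$n_features, config$baseline_meanlog,
                     config$baseline_sdlog)
  donor_offset <- setNames(exp(rnorm(config$n_donors, 0, config$donor_sd)),
                           donors)

  n_samp <- nrow(design)
  lfc_mat <- matrix(0, n_samp, config$n_features,
                    dimnames = list(design$sample_id, feats))
  if (length(responders) > 0) {
    mult <- archetype_multiplier(rep(archetype_of, each = n_samp),
                                 rep(design$time, length(responders)))
    lfc_mat[, responders] <- config$effect_size * (dose_rank / max_rank) * mult
  }

  noise <- matrix(exp(rnorm(n_samp * config$n_features, 0, config$noise_sd)),
                  n_samp, config$n_features)
  intensities <- sweep(2^lfc_mat * noise, 2, baseline, `*`) *
    donor_offset[design$donor]

  samples <- dplyr::bind_cols(
    design[c("sample_id", "dose", "time", "donor", "batch")],
    as_tibble(intensities)
  )

  structure(
    list(samples = sample_table(samples),
         truth = list(responder_ids = responders,
                      archetype_of = archetype_of,
                      planted_lfc = planted_lfc)),
    class = "cf_simulation"
  )
}

#' Simulate planted temporal-archetype response profiles
#'
#' Generates the log2 fold-change profiles of a set of dose-responders
#' directly: each feature's profile across the treated (dose, time)
#' conditions is its archetype pattern times a dose ramp of maximum
#' `effect_size`, plus i.i.d. Gaussian noise on the log2 scale. This is the
#' clustering stage's view of the data with the estimation step idealised;
#' use [simulate_feature_table()] for the full intensity-level emulation.
#'
#' The default `noise_sd` is the log2 fold-change estimation noise implied
#' by the intensity model defaults: lognormal intensity noise of sigma 0.1
#' averaged over 3 donors in both the treated and the reference group gives
#' an lfc standard deviation of `0.1 * sqrt(2/3) / log(2)` (about 0.12).
#'
#' @param n_features Number of responder profiles.
#' @param archetype_weights Proportions over the seven archetypes
#'   (apportioned deterministically, as in [simulate_feature_table()]).
#' @param doses,times Treated doses and times defining the profile columns.
#' @param effect_size Maximum absolute log2 FC at the top dose.
#' @param noise_sd Gaussian sd added to each profile entry (log2 scale).
#' @param seed Integer seed.
#' @return A list: `profiles` (matrix, features x conditions) and
#'   `archetype_of` (named character).
#' @export
simulate_archetype_profiles <- function(n_features = 40,
                                        archetype_weights = c(0.30, 0.25,
                                                              0.10, 0.10,
                                                              0.10, 0.075,
                                                              0.075),
                                        doses = c(0.5, 5, 50),
                                        times = c(4, 24),
                                        effect_size = 2,
                                        noise_sd = 0.1 * sqrt(2 / 3) /
                                          log(2),
                                        seed = 1L) {
  if (n_features < 2) abort("need at least 2 profiles")
  set.seed(seed)
  feats <- sprintf("F%04d", seq_len(n_features))
  counts <- apportion_archetypes(n_features,
                                 archetype_weights / sum(archetype_weights))
  archetype_of <- setNames(rep(response_archetypes()$archetype, counts),
                           feats)
  ramp <- effect_size * seq_along(doses) / length(doses)
  cond <- tidyr::expand_grid(time = times, dose = doses)
  base <- t(vapply(archetype_of, function(a) {
    rep(ramp, length(times)) * archetype_multiplier(a, rep(times,
                                                           each = length(doses)))
  }, numeric(nrow(cond))))
  profiles <- base + matrix(rnorm(length(base), 0, noise_sd),
                            nrow = nrow(base))
  dimnames(profiles) <- list(feats,
                             sprintf("dose%s_t%s", cond$dose, cond$time))
  list(profiles = profiles, archetype_of = archetype_of)
}

#' Simulate a measured isotopologue distribution
#'
#' Draws the label-count distribution of a product metabolite whose tracer
#' contribution is `contribution`: each molecule carries
#' `Binomial(n, contribution * E_max)` tracer-derived heavy atoms, where
#' `E_max` is the theoretical maximum mean enrichment of the atom-transfer
#' model under the tracer design (see [theoretical_max_enrichment()]). The
#' vector is then convolved with the natural-abundance pattern of the
#' tracer element and perturbed by multiplicative lognormal noise, i.e. it
#' is returned as an instrument would measure it. Correcting it with
#' [correct_natural_abundance()] recovers a vector whose mean enrichment is
#' `contribution * E_max` (exactly, at `noise_sd = 0`).
#'
#' @param design A [tracer_design()].
#' @param model An [atom_transfer_model()].
#' @param contribution Fractional contribution of the tracer substrate to
#'   the product pool, in `[0, 1]`.
#' @param noise_sd Lognormal sigma of per-isotopologue multiplicative noise.
#' @param seed Optional integer seed.
#' @return Numeric vector `(m0, ..., mn)` summing to 1.
#' @examples
#' v <- simulate_isotopologues(tracer_design_glucose12(),
#'                             model_lactate_from_glucose12(), 0.5)
#' mean_enrichment(correct_natural_abundance(v, 0.0107))
#' @export
simulate_isotopologues <- function(design, model, contribution,
                                   noise_sd = 0, seed = NULL) {
  if (contribution < 0 || contribution > 1) {
    abort("contribution must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- model$product_atoms
  e <- contribution * theoretical_max_enrichment(model, design)
  x <- dbinom(0:n, n, e)
  measured <- as.vector(correction_matrix(n, design$natural_abundance) %*% x)
  if (noise_sd > 0) {
    measured <- measured * exp(rnorm(n + 1, 0, noise_sd))
    measured <- measured / sum(measured)
  }
  measured
}

#' Simulate an extracellular-flux (Seahorse-style) run
#'
#' Emulates a mitochondrial stress test: per well, 6 basal measurement
#' cycles followed by 3 cycles after each sequential injection (oligomycin,
#' FCCP, rotenone + antimycin A), each cycle a mix-wait-measure step. Phase
#' means are the condition's basal value times the phase multiplier;
#' readings carry multiplicative lognormal noise.
#'
#' @param conditions A data frame with one row per condition: `condition`
#'   (label), `basal_ocr`, `basal_ecar` (per-well rates, pmol/min and
#'   mpH/min) and optional phase multipliers `ocr_oligomycin`, `ocr_fccp`,
#'   `ocr_rotaa`, `ecar_oligomycin`, `ecar_fccp`, `ecar_rotaa` (defaults
#'   0.5, 2, 0.1 for OCR and 1 for ECAR).
#' @param n_wells Wells per condition.
#' @param noise_sd Lognormal sigma of per-reading noise.
#' @param cells_per_well Cell count attached to each well.
#' @param cycles Named integer vector of cycles per phase.
#' @param seed Optional integer seed.
#' @return A tibble with columns `condition`, `well`, `cycle`, `phase`,
#'   `ocr`, `ecar`, `cells`, phases ordered
#'   basal -> oligomycin -> fccp -> rotaa.
#' @export
simulate_seahorse <- function(conditions, n_wells = 3, noise_sd = 0,
                              cells_per_well = 2e4,
                              cycles = c(basal = 6, oligomycin = 3,
                                         fccp = 3, rotaa = 3),
                              seed = NULL) {
  if (n_wells < 1) abort("n_wells must be >= 1")
  conditions <- as_tibble(conditions)
  defaults <- c(ocr_oligomycin = 0.5, ocr_fccp = 2, ocr_rotaa = 0.1,
                ecar_oligomycin = 1, ecar_fccp = 1, ecar_rotaa = 1)
  for (col in names(defaults)) {
    if (!col %in% names(conditions)) conditions[[col]] <- defaults[[col]]
  }
  mult <- as.matrix(conditions[paste0(rep(c("ocr_", "ecar_"), each = 3),
                                      c("oligomycin", "fccp", "rotaa"))])
  if (any(mult <= 0)) abort("phase multipliers must be > 0")
  if (!is.null(seed)) set.seed(seed)

  phase_seq <- rep(names(cycles), cycles)
  purrr::pmap_dfr(conditions, function(condition, basal_ocr, basal_ecar,
                                       ocr_oligomycin, ocr_fccp, ocr_rotaa,
                                       ecar_oligomycin, ecar_fccp, ecar_rotaa,
                                       ...) {
    ocr_mean <- c(basal = basal_ocr, oligomycin = basal_ocr * ocr_oligomycin,
                  fccp = basal_ocr * ocr_fccp, rotaa = basal_ocr * ocr_rotaa)
    ecar_mean <- c(basal = basal_ecar,
                   oligomycin = basal_ecar * ecar_oligomycin,
                   fccp = basal_ecar * ecar_fccp,
                   rotaa = basal_ecar * ecar_rotaa)
    tidyr::expand_grid(well = sprintf("w%02d", seq_len(n_wells)),
                       cycle = seq_along(phase_seq)) |>
      dplyr::mutate(
        condition = condition,
        phase = phase_seq[.data$cycle],
        ocr = ocr_mean[.data$phase] *
          exp(rnorm(dplyr::n(), 0, noise_sd)),
        ecar = ecar_mean[.data$phase] *
          exp(rnorm(dplyr::n(), 0, noise_sd)),
        cells = cells_per_well
      ) |>
      dplyr::select("condition", "well", "cycle", "phase", "ocr", "ecar",
                    "cells")
  })
}

#' Simulate a media metabolite time course
#'
#' Integrates per-cell exchange rates over an exponentially growing cell
#' population: for metabolite rate `r` (µmol per 10^6 cells per h, positive
#' = secretion), concentration at time `t` is
#' `C0 + r * I(t) / (1e6 * volume_ml)` where `I(t)` is the cumulative
#' cell-hours up to `t`. Negative concentrations are clipped to 0 with a
#' warning.
#'
#' @param rates Named numeric vector of exchange rates per metabolite
#'   (µmol per 10^6 cells per h).
#' @param c0 Named numeric vector of starting concentrations (mM), same
#'   names as `rates`.
#' @param cells0 Starting cell count (> 0).
#' @param growth Exponential growth rate (per h); 0 for a constant
#'   population.
#' @param volume_ml Culture volume in mL (> 0).
#' @param times Sampling times in hours (non-empty).
#' @param noise_sd Lognormal sigma of multiplicative concentration noise.
#' @param seed Optional integer seed.
#' @return A tibble `metabolite`, `time`, `concentration`, `volume_ml`,
#'   `cells`.
#' @export
simulate_media_timecourse <- function(rates, c0, cells0, growth = 0,
                                      volume_ml = 2, times = c(0, 24),
                                      noise_sd = 0, seed = NULL) {
  if (length(times) == 0) abort("times must be non-empty")
  if (volume_ml <= 0) abort("volume_ml must be > 0")
  if (cells0 <= 0) abort("cells0 must be > 0")
  if (is.null(names(rates)) || !setequal(names(rates), names(c0))) {
    abort("rates and c0 must be named identically")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- sort(times)
  cell_hours <- if (growth == 0) cells0 * times else
    cells0 * (exp(growth * times) - 1) / growth

  out <- tidyr::expand_grid(metabolite = names(rates), time = times) |>
    dplyr::mutate(
      concentration = c0[.data$metabolite] +
        rates[.data$metabolite] * cell_hours[match(.data$time, times)] /
          (1e6 * volume_ml),
      volume_ml = volume_ml,
      cells = cells0 * exp(growth * .data$time)
    )
  if (noise_sd > 0) {
    out$concentration <- out$concentration *
      exp(rnorm(nrow(out), 0, noise_sd))
  }
  if (any(out$concentration < 0)) {
    warn("negative simulated concentrations clipped to 0")
    out$concentration <- pmax(out$concentration, 0)
  }
  out
}
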