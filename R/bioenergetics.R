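#' Extract bioenergetic metrics from a mitochondrial stress test
#'
#' Summarises an OCR/ECAR cycle series (see [simulate_seahorse()] for the
#' expected columns) into the standard stress-test metrics, per condition:
#' \itemize{
#'   \item `basal_ocr`, `basal_ecar`: mean of the basal-phase cycles;
#'   \item `atp_linked_ocr`: drop in OCR after oligomycin
#'     (`basal - oligomycin phase`);
#'   \item `maximal_ocr`: FCCP-phase OCR (raw, without subtracting the
#'     non-mitochondrial component; set `subtract_nonmito = TRUE` for the
#'     alternative convention);
#'   \item `non_mito_ocr`: rotenone/antimycin-A-phase OCR;
#'   \item `proton_leak`: oligomycin-phase minus non-mitochondrial OCR;
#'   \item `spare_capacity`: maximal minus basal OCR;
#'   \item `atp_fraction`: ATP-linked over basal OCR.
#' }
#' All rates are normalised to cell number, giving per-cell units
#' (pmol min^-1 cell^-1, mpH min^-1 cell^-1). Metrics are computed per
#' well, then averaged within condition. A run whose maximal OCR falls
#' below basal triggers a warning, not an error.
#'
#' @param run Tibble with columns `condition`, `well`, `cycle`, `phase`
#'   (`basal`, `oligomycin`, `fccp`, `rotaa`), `ocr`, `ecar`, `cells`.
#' @param phase_summary How to summarise the 3 post-injection cycles of a
#'   phase: their `"mean"` (default, lowest variance), the `"last"` cycle,
#'   or the `"extremum"` (minimum for oligomycin/rotAA, maximum for FCCP).
#' @param subtract_nonmito Subtract non-mitochondrial OCR from maximal
#'   respiration.
#' @return A tibble of class `cf_bioenergetics`, one row per condition.
#' @export
extract_profile <- function(run, phase_summary = c("mean", "last",
                                                   "extremum"),
                            subtract_nonmito = FALSE) {
  phase_summary <- match.arg(phase_summary)
  run <- as_tibble(run)
  needed <- c("condition", "well", "cycle", "phase", "ocr", "ecar", "cells")
  missing <- setdiff(needed, names(run))
  if (length(missing) > 0) {
    abort(paste0("run lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(run$cells <= 0)) abort("cell counts must be > 0")
  phases <- c("basal", "oligomycin", "fccp", "rotaa")
  absent <- setdiff(phases, unique(run$phase))
  if (length(absent) > 0) {
    abort(paste0("missing phase(s): ", paste(absent, collapse = ", ")))
  }

  summarise_phase <- function(values, phase) {
    switch(phase_summary,
           mean = mean(values),
           last = values[length(values)],
           extremum = if (phase == "fccp") max(values) else min(values))
  }

  per_well <- run |>
    dplyr::arrange(.data$condition, .data$well, .data$cycle) |>
    dplyr::group_by(.data$condition, .data$well, .data$phase) |>
    dplyr::summarise(
      ocr = summarise_phase(.data$ocr, .data$phase[1]),
      ecar = summarise_phase(.data$ecar, .data$phase[1]),
      cells = .data$cells[1], .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "phase", values_from = c("ocr", "ecar"))

  profile <- per_well |>
    dplyr::mutate(
      basal_ocr = .data$ocr_basal / .data$cells,
      basal_ecar = .data$ecar_basal / .data$cells,
      atp_linked_ocr = (.data$ocr_basal - .data$ocr_oligomycin) /
        .data$cells,
      maximal_ocr = (.data$ocr_fccp -
                       if (subtract_nonmito) .data$ocr_rotaa else 0) /
        .data$cells,
      non_mito_ocr = .data$ocr_rotaa / .data$cells,
      proton_leak = (.data$ocr_oligomycin - .data$ocr_rotaa) / .data$cells,
      spare_capacity = .data$maximal_ocr - .data$basal_ocr,
      atp_fraction = .data$atp_linked_ocr / .data$basal_ocr
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(
      c("basal_ecar", "basal_ocr", "atp_linked_ocr", "maximal_ocr",
        "non_mito_ocr", "proton_leak", "spare_capacity", "atp_fraction"),
      mean), .groups = "drop")

  if (any(profile$maximal_ocr < profile$basal_ocr)) {
    warn("maximal OCR below basal OCR in at least one condition")
  }
  class(profile) <- c("cf_bioenergetics", class(profile))
  profile
}

#' @export
glance.cf_bioenergetics <- function(x, ...) {
  tibble(n_conditions = nrow(x),
         atp_fraction_range = diff(range(x$atp_fraction)))
}

#' Fold change of a treated metric over its control
#'
#' @param treated,control Metric values; `control` must be > 0.
#' @return `treated / control`.
#' @examples
#' fold_change(6.54, 3.36)
#' @export
fold_change <- function(treated, control) {
  if (any(control <= 0)) abort("control must be > 0")
  treated / control
}

#' Extracellular exchange rate from a media time course
#'
#' Converts the concentration change of a metabolite in spent media into a
#' per-cell exchange rate,
#' `rate = (C_end - C_start) * volume / (mean cells * dt)`,
#' using the arithmetic mean of the start and end cell counts. Positive
#' rates are secretion, negative rates uptake.
#'
#' @param tc Tibble with columns `metabolite`, `time` (h), `concentration`
#'   (mM), `volume_ml`, `cells`; at least 2 time points per metabolite.
#'   Only the first and last time points are used.
#' @return A tibble `metabolite`, `rate` (µmol per 10^6 cells per h), `dt`.
#' @examples
#' tc <- tibble::tibble(metabolite = "lactate", time = c(0, 24),
#'                      concentration = c(1, 2), volume_ml = 2,
#'                      cells = 1e6)
#' exchange_rate(tc)
#' @export
exchange_rate <- function(tc) {
  tc <- as_tibble(tc)
  needed <- c("metabolite", "time", "concentration", "volume_ml", "cells")
  missing <- setdiff(needed, names(tc))
  if (length(missing) > 0) {
    abort(paste0("time course lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tc |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(
      rate = {
        if (dplyr::n() < 2) abort("need >= 2 time points per metabolite")
        dt <- dplyr::last(.data$time) - dplyr::first(.data$time)
        if (dt == 0) abort("zero elapsed time")
        dc <- dplyr::last(.data$concentration) -
          dplyr::first(.data$concentration)
        n_bar <- (dplyr::first(.data$cells) + dplyr::last(.data$cells)) / 2
        dc * .data$volume_ml[1] / ((n_bar / 1e6) * dt)
      },
      dt = dplyr::last(.data$time) - dplyr::first(.data$time),
      .groups = "drop"
    )
}

#' Compare a bioenergetic metric between two condition groups
#'
#' Mann-Whitney U comparison of per-well or per-replicate metric values,
#' reporting the statistic, p-value and group medians (see
#' [mann_whitney_u()]).
#'
#' @param profiles_a,profiles_b Numeric metric values for the two groups.
#' @param alternative Passed to [mann_whitney_u()].
#' @return A tibble `U`, `p`, `n_a`, `n_b`, `median_a`, `median_b`.
#' @export
condition_compare <- function(profiles_a, profiles_b,
                              alternative = "two.sided") {
  mann_whitney_u(profiles_a, profiles_b, alternative = alternative)
}

#' Plot an extracellular-flux run
#'
#' OCR trace per well across measurement cycles with injection phases
#' shaded.
#'
#' @param run A cycle series as accepted by [extract_profile()].
#' @param measure `"ocr"` or `"ecar"`.
#' @return A ggplot object.
#' @export
plot_seahorse <- function(run, measure = c("ocr", "ecar")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(run, ggplot2::aes(x = .data$cycle,
                                    y = .data[[measure]],
                                    colour = .data$phase,
                                    group = .data$well)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "measurement cycle",
                  y = if (measure == "ocr") "OCR (pmol/min)"
                      else "ECAR (mpH/min)") +
    ggplot2::theme_minimal()
}
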