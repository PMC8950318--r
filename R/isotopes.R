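#' Tracer design
#'
#' Describes a stable-isotope labelling experiment: the tracer element, its
#' natural heavy-isotope abundance, the fraction of the substrate pool that
#' is tracer, the tracer's isotopic purity, and the labelled/total atom
#' counts of the tracer molecule.
#'
#' `tracer_design_glucose12()` is the preset for a 50:50 mixture of
#' unlabelled glucose and [1,2-13C2]glucose at 99% isotopic purity;
#' `tracer_design_glutamine15n2()` is the analogous [15N2]glutamine design.
#'
#' @param element `"C"` or `"N"`.
#' @param natural_abundance Natural abundance of the heavy isotope
#'   (defaults: 13C 0.0107, 15N 0.00364).
#' @param tracer_fraction Fraction of the substrate pool that is tracer, in
#'   `[0, 1]`.
#' @param purity Isotopic purity of the tracer's labelled positions.
#' @param labeled_positions Number of labelled atoms in the tracer molecule.
#' @param substrate_atoms Total atoms of the tracer element in the substrate.
#' @return A `tracer_design` list.
#' @export
tracer_design <- function(element = c("C", "N"),
                          natural_abundance = NULL,
                          tracer_fraction = 0.5,
                          purity = 0.99,
                          labeled_positions = 2,
                          substrate_atoms = 6) {
  element <- match.arg(element)
  natural_abundance <- natural_abundance %||%
    c(C = 0.0107, N = 0.00364)[[element]]
  vals <- c(natural_abundance, tracer_fraction, purity)
  if (any(vals < 0) || any(vals > 1)) {
    abort("abundance, tracer_fraction and purity must lie in [0, 1]")
  }
  if (labeled_positions > substrate_atoms) {
    abort("labeled_positions cannot exceed substrate_atoms")
  }
  structure(list(element = element, natural_abundance = natural_abundance,
                 tracer_fraction = tracer_fraction, purity = purity,
                 labeled_positions = labeled_positions,
                 substrate_atoms = substrate_atoms),
            class = "tracer_design")
}

#' @rdname tracer_design
#' @export
tracer_design_glucose12 <- function(tracer_fraction = 0.5, purity = 0.99) {
  tracer_design("C", tracer_fraction = tracer_fraction, purity = purity,
                labeled_positions = 2, substrate_atoms = 6)
}

#' @rdname tracer_design
#' @export
tracer_design_glutamine15n2 <- function(tracer_fraction = 0.5,
                                        purity = 0.99) {
  tracer_design("N", tracer_fraction = tracer_fraction, purity = purity,
                labeled_positions = 2, substrate_atoms = 2)
}

#' Atom-transfer models
#'
#' An atom-transfer model states how many tracer-derived heavy atoms a
#' product molecule carries, on average, when the substrate pool is *pure*
#' tracer (`expected_labeled_atoms`, averaged over the biochemical routes),
#' together with the product's atom count. Dilution by the unlabelled half
#' of the substrate pool and by tracer impurity is applied downstream by
#' [theoretical_max_enrichment()].
#'
#' Presets:
#' \describe{
#'   \item{`model_lactate_from_glucose12()`}{lactate from
#'     [1,2-13C2]glucose via glycolysis: glucose carbons 1-3 form one
#'     triose carrying both labels, carbons 4-6 the other carrying none, so
#'     a lactate molecule from pure tracer carries 1 label on average of
#'     its 3 carbons. The 16.5% theoretical-maximum enrichment of
#'     extracellular lactate under the 50:50, 99%-purity design follows.
#'     Purity is applied by default.}
#'   \item{`model_glutamate_from_glucose12()`}{glutamate from
#'     [1,2-13C2]glucose at complete TCA-cycle turnover: from pure tracer,
#'     half the acetyl-CoA pool is M2 (the labelled triose) and half M0, so
#'     at isotopic steady state each of glutamate's 5 carbons is labelled
#'     with probability 1/2 - 2.5 expected labels of 5. Under the 50:50
#'     design this gives the 25% maximum enrichment used for the
#'     glucose-to-glutamate carbon contribution; purity is not applied, by
#'     default, matching that worked value.}
#' }
#'
#' @param name Model label.
#' @param product_atoms Tracer-element atoms in the product molecule.
#' @param expected_labeled_atoms Expected tracer-derived heavy atoms per
#'   product molecule at pure tracer; must not exceed `product_atoms`.
#' @param apply_purity Default for the purity factor in
#'   [theoretical_max_enrichment()].
#' @return An `atom_transfer_model` list.
#' @export
atom_transfer_model <- function(name, product_atoms, expected_labeled_atoms,
                                apply_purity = TRUE) {
  if (product_atoms < 1) abort("product_atoms must be >= 1")
  if (expected_labeled_atoms < 0 ||
      expected_labeled_atoms > product_atoms) {
    abort("expected_labeled_atoms must lie in [0, product_atoms]")
  }
  structure(list(name = name, product_atoms = product_atoms,
                 expected_labeled_atoms = expected_labeled_atoms,
                 apply_purity = apply_purity),
            class = "atom_transfer_model")
}

#' @rdname atom_transfer_model
#' @export
model_lactate_from_glucose12 <- function() {
  atom_transfer_model("lactate_from_glucose12", product_atoms = 3,
                      expected_labeled_atoms = 1, apply_purity = TRUE)
}

#' @rdname atom_transfer_model
#' @export
model_glutamate_from_glucose12 <- function() {
  atom_transfer_model("glutamate_from_glucose12_complete_turnover",
                      product_atoms = 5, expected_labeled_atoms = 2.5,
                      apply_purity = FALSE)
}

validate_isotopologue_vector <- function(v, tol = 1e-6) {
  if (length(v) < 2) abort("isotopologue vector needs at least m0 and m1")
  if (any(v < -tol)) abort("isotopologue fractions must be >= 0")
  if (abs(sum(v) - 1) > tol) abort("isotopologue fractions must sum to 1")
  invisible(v)
}

#' Natural-abundance convolution matrix
#'
#' Entry (i, j) is the probability that a molecule carrying `j` tracer
#' labels is measured with `i` heavy atoms because `i - j` of its `n - j`
#' unlabelled positions carry a naturally occurring heavy isotope:
#' `C(n-j, i-j) a^(i-j) (1-a)^(n-i)` for `i >= j`, 0 otherwise. Columns
#' sum to 1. Multiplying a true label-count distribution by this matrix
#' gives the measured distribution.
#'
#' @param n Atom count of the measured metabolite (>= 1).
#' @param a Natural abundance of the heavy isotope, in `[0, 1)`.
#' @return Dense `(n+1) x (n+1)` matrix.
#' @examples
#' correction_matrix(1, 0.0107)
#' @export
correction_matrix <- function(n, a) {
  if (n < 1) abort("n must be >= 1")
  if (a < 0 || a >= 1) abort("natural abundance must lie in [0, 1)")
  m <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    i <- j:n
    m[i + 1, j + 1] <- dbinom(i - j, n - j, a)
  }
  m
}

#' Correct a measured isotopologue vector for natural abundance
#'
#' Deconvolves the naturally occurring heavy-isotope contribution from a
#' measured isotopologue distribution by solving
#' `correction_matrix(n, a) x = measured` under `x >= 0` (non-negative
#' least squares, so noisy data cannot produce negative fractions), then
#' renormalising `x` to sum 1. The result is the distribution of
#' tracer-derived labels only.
#'
#' @param measured Numeric vector `(m0, ..., mn)` of measured fractions
#'   summing to 1.
#' @param a Natural abundance of the heavy isotope of the tracer element.
#' @param residual_tol Warn if the NNLS residual (2-norm) exceeds this.
#' @return Corrected vector of the same length, non-negative, summing to 1.
#' @examples
#' measured <- as.vector(correction_matrix(3, 0.0107) %*% c(0.6, 0, 0.4, 0))
#' correct_natural_abundance(measured, 0.0107)
#' @export
correct_natural_abundance <- function(measured, a, residual_tol = 1e-3) {
  validate_isotopologue_vector(measured)
  if (a == 0) return(measured / sum(measured))
  n <- length(measured) - 1
  fit <- pracma::lsqnonneg(correction_matrix(n, a), measured)
  x <- fit$x
  resid <- sqrt(sum((correction_matrix(n, a) %*% x - measured)^2))
  if (resid > residual_tol) {
    warn(sprintf(
      "natural-abundance correction residual %.3g exceeds tolerance %.3g",
      resid, residual_tol))
  }
  x / sum(x)
}

#' Mean isotopic enrichment
#'
#' The label-count-weighted average fraction of heavy atoms per molecule,
#' `sum(i * m_i) / n`: 0 for a fully unlabelled pool, 1 for a fully
#' labelled one.
#'
#' @param v Isotopologue vector `(m0, ..., mn)` summing to 1.
#' @return Enrichment fraction in `[0, 1]`.
#' @examples
#' mean_enrichment(c(0.5, 0.25, 0.25))
#' @export
mean_enrichment <- function(v) {
  validate_isotopologue_vector(v)
  n <- length(v) - 1
  sum((0:n) * v) / n
}

#' Theoretical maximum mean enrichment under a tracer design
#'
#' The mean enrichment a product metabolite would reach if the tracer
#' substrate were its sole precursor:
#' `E_max = f * (purity if applied) * expected_labeled_atoms / product_atoms`
#' with `f` the tracer fraction of the substrate pool. For the lactate
#' preset under the 50:50 [1,2-13C2]glucose design at 99% purity this is
#' `0.5 * 0.99 * 1/3 = 16.5%`.
#'
#' @param model An [atom_transfer_model()].
#' @param design A [tracer_design()].
#' @param apply_purity Multiply in the tracer purity; defaults to the
#'   model's own convention (the two worked contributions in this system
#'   use different conventions, see the model presets).
#' @return Enrichment fraction.
#' @examples
#' theoretical_max_enrichment(model_lactate_from_glucose12(),
#'                            tracer_design_glucose12())
#' @export
theoretical_max_enrichment <- function(model, design,
                                       apply_purity = NULL) {
  stopifnot(inherits(model, "atom_transfer_model"),
            inherits(design, "tracer_design"))
  apply_purity <- apply_purity %||% model$apply_purity
  design$tracer_fraction * (if (apply_purity) design$purity else 1) *
    model$expected_labeled_atoms / model$product_atoms
}

#' Fractional contribution of a tracer substrate to a product pool
#'
#' The observed mean enrichment as a fraction of the theoretical maximum,
#' `c = E_obs / E_max`, clipped to `[0, 1]` with a warning when the
#' observation exceeds the maximum.
#'
#' @param e_obs Observed mean enrichment fraction.
#' @param e_max Theoretical maximum enrichment (> 0), e.g. from
#'   [theoretical_max_enrichment()].
#' @return Contribution fraction in `[0, 1]`.
#' @examples
#' fractional_contribution(0.0448, 0.25)  # glucose -> glutamate carbon
#' @export
fractional_contribution <- function(e_obs, e_max) {
  if (e_max <= 0) abort("e_max must be > 0")
  c_raw <- e_obs / e_max
  if (c_raw > 1) {
    warn(sprintf("contribution %.3f > 1 clipped to 1", c_raw))
    c_raw <- 1
  }
  max(c_raw, 0)
}

#' Contribution corrected for a pre-existing unlabelled pool
#'
#' When a fraction `phi` of the measured pool was already present before
#' labelling began (e.g. lactate in fresh media), the enrichment of the
#' newly made material is `E_obs / (1 - phi)`, and the contribution
#' becomes `c = (E_obs / (1 - phi)) / E_max`.
#'
#' @param e_obs Observed mean enrichment fraction.
#' @param phi Pre-existing (unlabelled) fraction of the measured pool, in
#'   `[0, 1)`.
#' @param e_max Theoretical maximum enrichment (> 0).
#' @return Contribution fraction in `[0, 1]` (clipped with warning as in
#'   [fractional_contribution()]).
#' @export
contribution_with_preexisting_pool <- function(e_obs, phi, e_max) {
  if (phi < 0 || phi >= 1) abort("phi must lie in [0, 1)")
  fractional_contribution(e_obs / (1 - phi), e_max)
}

#' Pentose-phosphate pathway split ratio from lactate isotopologues
#'
#' Under [1,2-13C2]glucose, lactate made through glycolysis is M2 while
#' lactate whose glucose traversed the oxidative pentose phosphate pathway
#' loses the C1 label as CO2 and emerges M1. The `"lee"` estimator (the
#' classic pentose-cycle formula) is `PC = (m1/m2) / (3 + m1/m2)`; the
#' `"simple"` estimator is the plain ratio `m1 / (m1 + m2)`.
#'
#' @param m1,m2 Corrected M1 and M2 fractional abundances of lactate
#'   (non-negative, not both 0).
#' @param estimator `"lee"` (default), `"simple"` or `"all"` for both.
#' @return The PPP fraction, or a tibble of both estimates for `"all"`.
#' @examples
#' ppp_fraction(0.01, 0.5)
#' @export
ppp_fraction <- function(m1, m2, estimator = c("lee", "simple", "all")) {
  estimator <- match.arg(estimator)
  if (m1 < 0 || m2 < 0 || (m1 == 0 && m2 == 0)) {
    abort("m1 and m2 must be >= 0 and not both 0")
  }
  lee <- function() {
    if (m2 == 0) abort("lee estimator undefined for m2 = 0")
    ratio <- m1 / m2
    ratio / (3 + ratio)
  }
  simple <- function() m1 / (m1 + m2)
  switch(estimator,
         lee = lee(),
         simple = simple(),
         all = tibble(estimator = c("lee", "simple"),
                      ppp_fraction = c(lee(), simple())))
}

#' Summarise labelling of one metabolite
#'
#' Convenience wrapper running the full enrichment chain on one measured
#' isotopologue vector: natural-abundance correction, mean enrichment,
#' theoretical maximum under the given design/model, and fractional
#' contribution (optionally corrected for a pre-existing pool).
#'
#' @param measured Measured isotopologue vector `(m0, ..., mn)`.
#' @param design A [tracer_design()].
#' @param model An [atom_transfer_model()] with
#'   `product_atoms = length(measured) - 1`.
#' @param phi Pre-existing unlabelled pool fraction (default 0).
#' @param apply_purity Override the model's purity convention.
#' @return A one-row tibble `metabolite`, `mean_enrichment`,
#'   `theoretical_max`, `contribution`, `phi`.
#' @export
enrichment_summary <- function(measured, design, model, phi = 0,
                               apply_purity = NULL) {
  if (model$product_atoms != length(measured) - 1) {
    abort("model product_atoms does not match isotopologue vector length")
  }
  corrected <- correct_natural_abundance(measured, design$natural_abundance)
  e <- mean_enrichment(corrected)
  e_max <- theoretical_max_enrichment(model, design, apply_purity)
  tibble(metabolite = model$name, mean_enrichment = e,
         theoretical_max = e_max,
         contribution = contribution_with_preexisting_pool(e, phi, e_max),
         phi = phi)
}
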