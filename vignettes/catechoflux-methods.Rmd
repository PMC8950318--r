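---
title: "Methods: dose-response metabolomics, tracing and bioenergetics in catechoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response metabolomics, tracing and bioenergetics in catechoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catechoflux)
```

`catechoflux` analyses how catecholamine stimulation (equimolar adrenaline
and noradrenaline at 0, 0.5, 5 and 50 µM) reshapes endothelial-cell
metabolism, from four kinds of input: LC-MS feature tables, isotopologue
distributions from stable-isotope tracing, extracellular-flux (OCR/ECAR)
cycle series, and media concentration time courses. This vignette documents
the statistical models, the parameters that matter, the synthetic-data
generator that stands in for instrument data, and the numerical and design
choices behind the implementation.

## Dose-response feature selection

The feature-table model is multiplicative: measured intensity is a
feature-specific baseline, times the treatment effect `2^lfc`, times a
per-donor offset, times lognormal measurement noise. Accordingly:

* **Quantile normalization** (`quantile_normalize()`) maps every sample
  onto the across-sample mean of sorted intensity vectors, removing
  sample-wide distributional (batch/donor) shifts. It is idempotent, and
  ties receive the mean of the reference values at the tied ranks.
* **Fold changes** (`log2_fold_change()`) compare each (dose, time)
  condition with the dose-0 samples *at the same time point*, pooling
  donors into the means on both sides. Whether one should average per
  donor first is genuinely open; pooled means are the stated convention
  here. A pseudo-intensity (default: half the smallest nonzero intensity
  in the table) keeps the log finite when zeros occur.
* **Selection** (`select_responders()`) requires, at 4 h *or* 24 h, all
  of: max |log2 FC| > 1 across treated doses; |Pearson r| > 0.8 with
  p < 0.05 between log2 intensity and the encoded dose; and a Wald test
  of the regression slope with p < 0.05. Thresholds are arguments; the
  defaults are the study's gates.

Two deliberate choices need stating. First, the **dose encoding**: the
doses are decade-spaced with a zero, so raw-scale correlation would be
dominated entirely by the 50 µM point. The default is the ordinal encoding
(0, 1, 2, 3); `"log10"` and `"raw"` are available (`encode_dose()`).
Second, the correlation gate is applied to **|r|**, not signed r: metabolites
depleted in a dose-dependent way (the largest temporal cluster is a
down-at-4-h pattern) must be selectable, which a one-sided gate would
forbid.

No multiple-testing correction is applied across features by default,
matching the study design; the per-feature p-values are reported so users
can apply `p.adjust` downstream if they wish.

## Temporal clustering and model selection

Responder profiles — log2 FC across the six treated (dose, time)
conditions — are clustered agglomeratively (`cluster_profiles()`) under
**cosine distance** with **complete linkage**: cosine groups profiles by
response *shape* irrespective of magnitude, which is what the temporal
archetypes are. The number of clusters is chosen by scanning cuts of the
dendrogram and minimizing the **Davies-Bouldin index**
(`davies_bouldin()`, `optimal_partition()`), computed with Euclidean
geometry on the profile coordinates; ties go to the smallest k, and the
default scan range 2..min(12, n−1) brackets the seven observed archetypes
with margin. Coincident centroids make the index infinite — such cuts can
never win. Determinism of the merge order follows from `stats::hclust()`
given a fixed input order; permuting the input rows permutes the labels
equivalently.

## Stable-isotope arithmetic

For a metabolite with `n` atoms of the tracer element, the measured
isotopologue vector `(m0, ..., mn)` mixes biological labelling with
naturally occurring heavy isotopes. The forward process is linear: the
measured vector is `M x`, where `x` is the tracer-label distribution and
`M` the binomial convolution matrix (`correction_matrix()`), whose (i, j)
entry is the probability that `i - j` of `n - j` unlabelled positions are
naturally heavy. Correction (`correct_natural_abundance()`) inverts this
by **non-negative least squares** rather than direct matrix inversion:
`M` is well-conditioned, but on noisy data inversion can yield (small)
negative fractions, which NNLS structurally excludes; the solution is then
renormalized to sum 1 and the fit residual is reported as a warning when
it exceeds `residual_tol`. Only the tracer element's natural abundance is
corrected (¹³C 0.0107, ¹⁵N 0.00364), the appropriate assumption for
low-resolution qTOF data.

Mean enrichment is `E = Σ i·m_i / n`. The **theoretical maximum**
enrichment under a tracer design is

    E_max = f · (π) · expected_labeled_atoms / product_atoms

where `f` is the tracer fraction of the substrate pool, `π` the isotopic
purity, and `expected_labeled_atoms` the mean number of tracer-derived
labels a product molecule carries **when the substrate pool is pure
tracer**. Anchoring the atom-transfer presets at pure tracer keeps `f`
and `π` out of the model definition and in the design where they belong:

* *Lactate from [1,2-¹³C₂]glucose*: glucose carbons 1-3 form one triose
  carrying both labels, carbons 4-6 the other carrying none, so the
  expected labels per 3-carbon lactate are 1. With `f = 0.5`, `π = 0.99`:
  `E_max = 0.5 · 0.99 · 1/3 = 16.5%`.
* *Glutamate from [1,2-¹³C₂]glucose at complete TCA turnover*: from pure
  tracer, half the acetyl-CoA pool is M2, so at isotopic steady state each
  of glutamate's five carbons is labelled with probability 1/2 — 2.5
  expected labels. With `f = 0.5`: `E_max = 25%`.

The two published worked values use different purity conventions — the
lactate maximum includes `π`, the glutamate-derived contribution does not
(25% exactly) — so each preset carries its own `apply_purity` default and
the flag can be overridden per call. This inconsistency is inherited from
the worked examples themselves and is surfaced rather than hidden.

Contributions are `c = E_obs / E_max` (`fractional_contribution()`),
clipped to [0, 1] with a warning; with a pre-existing unlabelled pool
fraction φ (e.g. lactate already in fresh media),
`c = (E_obs / (1 − φ)) / E_max`. φ must be supplied by the user — it is a
property of the media lot, not of the algebra.

The **pentose-phosphate split ratio** (`ppp_fraction()`) uses corrected
lactate M1/M2: glycolytic lactate is M2, lactate whose glucose passed the
oxidative PPP loses the C1 label and emerges M1. The default `"lee"`
estimator is the classic pentose-cycle formula
`PC = (m1/m2) / (3 + m1/m2)`; the `"simple"` ratio `m1/(m1+m2)` is kept
because published "~2%"-scale values cannot disambiguate the variant.

## Bioenergetics and exchange rates

`extract_profile()` reduces a stress-test run (6 basal cycles, then 3
after each of oligomycin, FCCP, rotenone + antimycin A) to per-cell
metrics: basal ECAR/OCR, ATP-linked OCR (basal − oligomycin), maximal OCR
(FCCP phase, *raw* by default — the published fold changes use raw FCCP
values; `subtract_nonmito = TRUE` gives the alternative convention),
non-mitochondrial OCR (rot/AA phase), proton leak (oligomycin − rot/AA),
spare capacity and the ATP fraction (ATP-linked / basal). The identity
`basal = ATP-linked + leak + non-mitochondrial` holds exactly by
construction. Post-injection phases are summarized by the **mean** of
their three cycles (lowest variance; `"last"` and `"extremum"` are
options since the convention is rarely stated). Metrics are computed per
well, normalized by cell count, then averaged within condition.

`exchange_rate()` converts a media concentration change into
µmol·(10⁶ cells)⁻¹·h⁻¹ via
`rate = ΔC · V / (N̄ · Δt)`, with `N̄` the arithmetic mean of start and
end cell counts (cultures grow over 24 h and a single counting well per
experiment gives only endpoints; for growth up to ~20% per interval the
endpoint mean differs from the exact exponential time-average by < 1%).
Positive rates are secretion, negative uptake.

Group comparisons everywhere use the **Mann-Whitney U test**
(`mann_whitney_u()`): exact p-values when both groups have ≤ 8 untied
observations, the normal approximation with tie and continuity correction
otherwise.

## The synthetic-data generator

Every input type has a generator with known ground truth:

* `simulate_feature_table()` emulates the design — 4 doses × 3 times ×
  3 donors, 500 features by default with 40 planted responders. Planted
  log2 FC is log-linear in ordinal dose and follows one of **seven
  temporal archetypes** (down-then-rebound, up-at-both, up-then-down,
  down-then-up, early-up-only, late-down-only, late-up-only), apportioned
  deterministically by weights (0.30, 0.25, 0.10, 0.10, 0.10, 0.075,
  0.075) that mirror the observed cluster-size ordering: the study does
  not report counts, so these are the package's fixed defaults, not the
  study's values. The same applies to the noise defaults (lognormal
  σ = 0.1 multiplicative noise, σ = 0.2 per-donor offset, lognormal
  baselines): per-feature variances are not published, so these are
  realistic, user-tunable defaults. Donor offsets are shared across all
  features of a sample, which is exactly the kind of shift quantile
  normalization removes.
* `simulate_archetype_profiles()` generates the clustering stage's input
  directly: planted archetype profiles plus Gaussian log2-FC noise whose
  default (0.1·√(2/3)/ln 2 ≈ 0.12) is the fold-change estimation noise
  implied by the intensity-model defaults (σ = 0.1 noise averaged over 3
  donors in both the treated and reference groups).
* `simulate_isotopologues()` draws label counts as Binomial(n, c·E_max)
  per molecule, convolves with natural abundance and adds multiplicative
  noise. This matches the mean-enrichment contract exactly but is **not
  positionally exact**: real lactate under [1,2-¹³C₂]glucose is
  M0/M2-heavy, not binomial. Positional isotopomer modelling is out of
  scope, so the PPP estimators should be exercised on constructed M1/M2
  values, not on this generator's output.
* `simulate_seahorse()` and `simulate_media_timecourse()` reproduce the
  cycle structure and the rate-integration model that their estimators
  invert; at zero noise every generator/estimator pair round-trips
  exactly (tolerance 1e-9 in the tests).

One RNG stream per generator, seeded from its config, makes each stage
reproducible in isolation; identical configurations give bit-identical
outputs.

### What passing on synthetic data does and does not show

The generator's effects are exactly log-linear in ordinal dose and its
noise is exactly lognormal, so selection on synthetic data is close to an
oracle setting: with the default conditions (500 features, 40 responders,
effect size 2, noise 0.1, 3 donors) sensitivity and precision are ≈ 1, and
the Davies-Bouldin scan on planted archetype profiles recovers k = 7 in
essentially all seeds at the derived noise level (and still in ~88% at a
noise level nearly twice as large). Real data have correlated features,
drift, missingness and non-monotone dose responses that the generator
deliberately omits; the synthetic results validate the *implementation*,
not the field performance of the gates.

Two end-to-end behaviours are worth knowing about. Quantile normalization
**rank-pins** features at the extremes: a feature that is the largest (or
smallest) value in every sample receives the same reference value
everywhere, so its fold changes collapse to exactly zero and it becomes
undetectable — an inherent cost of the method, visible in the simulation
when a planted responder lands on an extreme baseline. And when the
cluster scan is run on *selected* (rather than planted) features, an
occasional false positive — whose profile is pure noise with an arbitrary
direction — tends to form a singleton cluster and inflate the chosen k by
one. Both effects are properties of the pipeline a user should expect on
real data as well.

## Numerical choices and problem sizes

Degenerate inputs are defined, not accidental: constant feature columns
report r = 0, p = 1; zero-residual exact fits report a Wald p of 0; a
constant encoded dose is an error; all-zero profiles are rejected before
cosine distance; coincident centroids give an infinite Davies-Bouldin
index with a warning; contributions above 1 are clipped with a warning.
The vectorised per-feature correlation/regression path is checked against
the scalar `cor.test`/`lm` route in the tests at tolerance 1e-10.

The test suite and the acceptance script run at the design's own scale —
36-sample tables with 80-500 features, 40-profile cluster scans over 50
seeds, 15-cycle stress-test runs — chosen so the full pipeline remains a
desk-scale computation while exercising every stage at the study's
dimensions.

## Known limitations

* The pre-existing-pool fraction φ and the tracer purity are inputs, not
  estimates; the package does not infer them from data.
* No positional (isotopomer) modelling and no metabolic flux fitting; the
  atom-transfer presets cover the two canonical products, and other
  models must be supplied via `atom_transfer_model()`.
* Clustering assumes profiles have a meaningful direction; features with
  near-zero response should be filtered (the selection stage does this)
  before cosine distance.
* The Wald and Pearson gates on the same simple regression are largely
  redundant (identical p-values in the balanced case); both are applied
  and reported because both are part of the stated selection rule.
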