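# catechoflux

Catecholamines (adrenaline and noradrenaline) released during acute stress
reshape the metabolism of the vascular endothelium. `catechoflux` implements
the computational side of a dose–response study of catecholamine-stimulated
human endothelial cells (HUVECs): it takes untargeted LC–MS feature tables,
stable-isotope isotopologue measurements, extracellular-flux (Seahorse-style
OCR/ECAR) cycle series and spent-media concentration time courses, and turns
them into dose-responding metabolite sets, temporal response clusters,
tracer-derived carbon/nitrogen contributions, bioenergetic metrics and
per-cell exchange rates.

The package is tidyverse-native: every user-facing function takes a data
frame first and returns a tibble, results carry `tidy()`/`glance()` methods,
and each result type has an `autoplot()`/`plot_*()` figure. A synthetic-data
generator reproduces the full experimental design with known ground truth,
so the entire pipeline is testable without access to the original
instrument data.

## The methods in brief

**Dose–response selection.** Feature intensities are quantile-normalized
across samples (the batch remedy), then log2 fold changes are computed per
(dose, time) condition against same-time unstimulated controls, pooling
donors:

```
lfc(d, t, feature) = log2( (mean treated + pseudo) / (mean dose-0 at t + pseudo) )
```

A feature is a *dose-responder* if, at 4 h or 24 h, it clears three joint
gates: max |log2 FC| > 1 across treated doses, |Pearson r| > 0.8 (p < 0.05)
between log2 intensity and the ordinally encoded dose (0, 0.5, 5, 50 µM →
0, 1, 2, 3), and a significant Wald test of the regression slope
(p < 0.05).

**Temporal clustering.** Responder profiles (log2 FC across treated
dose × time conditions) are clustered agglomeratively under cosine distance
with complete linkage, and the partition is chosen by minimizing the
Davies–Bouldin index

```
DB = mean_i max_{j≠i} (S_i + S_j) / M_ij
```

with `S` the mean within-cluster distance to centroid and `M` the centroid
separation.

**Stable-isotope tracing.** Measured isotopologue vectors `(m0, …, mn)` are
corrected for natural abundance by non-negative least squares against the
binomial convolution matrix, summarized as mean enrichment
`E = Σ i·m_i / n`, and compared with the theoretical maximum under the
tracer design,

```
E_max = f · π · expected_labeled_atoms / product_atoms
```

(`f` tracer fraction, `π` purity). The fractional contribution of the
tracer substrate is `c = E_obs / E_max`, optionally corrected for a
pre-existing unlabelled pool (`c = (E_obs / (1 − φ)) / E_max`). The
pentose-phosphate split ratio is estimated from lactate M1/M2 under
[1,2-¹³C₂]glucose.

**Bioenergetics.** Mitochondrial stress-test cycle series (6 basal + 3
cycles after each of oligomycin, FCCP, rotenone/antimycin A) are reduced to
per-cell basal/maximal/ATP-linked/non-mitochondrial OCR, proton leak, spare
capacity and basal ECAR; media time courses give per-cell exchange rates
(positive = secretion).

## Worked example

```r
library(catechoflux)

# --- tracer arithmetic ---------------------------------------------------
design <- tracer_design_glucose12()          # 50:50 mix, 99% purity
e_max  <- theoretical_max_enrichment(model_lactate_from_glucose12(), design)
sprintf("theoretical max lactate enrichment: %.1f%%", 100 * e_max)
#> "theoretical max lactate enrichment: 16.5%"

measured  <- simulate_isotopologues(design, model_lactate_from_glucose12(),
                                    contribution = 0.82, noise_sd = 0.01,
                                    seed = 2)
round(measured, 4)
#> [1] 0.6230 0.3193 0.0547 0.0030
corrected <- correct_natural_abundance(measured, design$natural_abundance)
mean_enrichment(corrected)                       # 0.137
fractional_contribution(mean_enrichment(corrected), e_max)  # 0.828

# --- dose-response pipeline ----------------------------------------------
sim  <- simulate_feature_table(simulation_config(seed = 7))
norm <- quantile_normalize(sim$samples)
fc   <- log2_fold_change(norm)
res  <- select_responders(fc, norm)
glance(res)
#>   n_features n_selected n_times
#> 1        500         40       2

selection_performance(selected_features(res), sim$truth)
#>   sensitivity precision n_selected n_planted
#> 1           1         1         40        40

part <- optimal_partition(profile_matrix(fc, features = selected_features(res)))
part
#> Optimal partition: k = 7 clusters (Davies-Bouldin 0.268) over 40 profiles
#>  1  2  3  4  5  6  7
#> 12 10  4  4  4  3  3
autoplot(part)   # clustered log2-FC heatmap
```

The simulated table plants 40 dose-responders among 500 features across
4 doses × 3 times × 3 donors; the selection recovers all 40 with no false
positives, and the Davies–Bouldin scan recovers the seven planted temporal
archetypes.

`run_pipeline(pipeline_config(...))` executes the whole chain
(simulate/read → normalize → fold change → select → cluster) and writes
stage tables plus a JSON manifest for reproducible reruns.

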