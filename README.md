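# synerscreen

Analysis toolkit for high-throughput drug-combination viability screens on
patient-derived tumor cell cultures, of the kind used to find combination
partners for a targeted agent (e.g. a MEK inhibitor) across a cohort of
patient-derived head-and-neck cancer lines, and to carry the winning regimen
into xenograft validation.

`synerscreen` covers the full analysis chain:

- **Plates** — reading well-level CSVs, normalizing raw absorbance to no-drug
  control wells, and assembling 7×7 combination dose matrices with embedded
  single-agent margins.
- **Single-agent dose–response** — Hill-equation fitting
  `v(c) = E_inf + (E_0 − E_inf) / (1 + (c/IC50)^h)` by deterministic
  multi-start gradient-based least squares; agents that never reach 50%
  inhibition within the tested range get the censored inequality
  `IC50 ≥ max_conc`, which propagates into all downstream synergy statistics;
  normalized AUC over log10 dose (AUC = 1 ⇔ no drug effect).
- **Combination surfaces** — an exact Gaussian-process regression of
  viability on the two log-dose coordinates (RBF kernel, per-axis
  length-scales, hyperparameters by gradient ascent on the log marginal
  likelihood), with iso-effect contour extraction confined to the measured
  dose box.
- **Synergy** — the Chou–Talalay Combination Index
  `CI = C_A/IC_xx_A + C_B/IC_xx_B` evaluated along GP iso-effect contours
  (CI < 1 synergy), identification of the minimum-CI optimal dosing regimen,
  and the Bliss beta coefficient: the origin-constrained least-squares slope
  of observed vs Bliss-expected inhibition
  `E_bliss = 1 − (1 − f_A)(1 − f_B)` (beta = 1 additive, > 1 synergistic).
- **RPPA differential affinity** — validated-antibody filtering and an
  empirical-Bayes moderated t-test (variances shrunk toward a moment-matched
  inverse-chi-square prior) with Benjamini–Hochberg FDR control and
  direction-stratified set comparisons across timepoints or sensitivity
  classes.
- **Xenografts** — caliper volumes `L·W²/2`, day-wise group summaries,
  percent tumor-volume reduction, and Student's t group comparisons.
- **Synthetic data** — seeded generators for every input above (plates,
  Bliss-/Loewe-/synergy-mode combination grids, RPPA matrices with planted
  effects, growth curves), each returning its ground truth, so the whole
  pipeline is testable without patient data.

## Worked example

Score a synthetic combination screen with a mildly synergistic pair
(ground-truth synergy multiplier 1.3 over Bliss):

```r
library(synerscreen)
spec <- generator_spec(seed = 42, noise_sd = 0.05,
                       hill_a = list(ic50 = 0.005, slope = 1.2, e0 = 1, e_inf = 0.05),
                       hill_b = list(ic50 = 0.2,   slope = 1.0, e0 = 1, e_inf = 0.10),
                       surface_mode = "synergy", synergy_strength = 0.3)

## single-agent dose-response: 13-point three-fold series from 10 uM
series <- build_single_agent_series("trametinib", top_conc = 10, n_points = 13, dilution = 3)
plate  <- gen_single_agent_plate(spec, series)
wells  <- normalize_to_control(plate$wells)
curve  <- dose_response_curve("trametinib", "line10004",
                              wells$conc_a[!wells$is_control],
                              wells$viability[!wells$is_control])
fit_a <- fit_hill(curve)
fit_a
#> <hill_fit> trametinib: IC50 = 0.005344 uM, slope 1.26, e0 1.06, e_inf 0.0739, mse 0.00265
compute_auc(curve)$auc
#> 0.497

## 7x7 combination screen and synergy scores
combo <- gen_combination_grid(spec, build_combination_axis(0.03), build_combination_axis(1),
                              drug_a = "trametinib", drug_b = "GDC-0032")
compute_bliss_beta(combo$grid)
#> Bliss beta = 1.16 over 36 combination cells

surface <- fit_gp_surface(combo$grid)
ci   <- ci_over_grid(surface, fit_a, fit_b)   # fit_b: the partner's Hill fit
best <- min_ci_regimen(ci)
#> minimum CI = 0.28 at 0.0031 uM trametinib + 0.106 uM GDC-0032 (75% inhibition)
```

The fitted IC50 (0.0053 µM) recovers the planted 0.005 µM despite 5%
viability noise; the AUC of 0.50 marks a strongly responsive line (1 would
be no effect). Both synergy models agree on this pair: Bliss beta 1.16 > 1
and a minimum Combination Index of 0.28 < 1, with the minimum-CI regimen
naming the dose pair a follow-up (e.g. xenograft) experiment should use.

See the vignette in `vignettes/combination-screen-analysis.Rmd` for the
models, their assumptions, and all tuning parameters.

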