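---
title: "Models and methods for combination-screen synergy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for combination-screen synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synerscreen)
```

`synerscreen` analyzes high-throughput viability screens in which a backbone
drug is combined pairwise with candidate partners on patient-derived tumor
cells, and answers three questions: how sensitive is each line to each single
agent, which combinations are synergistic, and at which doses. This vignette
documents the models, their assumptions, every tunable parameter that
matters, and the limits of what the bundled synthetic data can demonstrate.

## Plate normalization

Raw absorbance from the metabolic (MTS-type) readout is converted to a
viability fraction by dividing each well by the mean of the no-drug control
wells on the same plate (`normalize_to_control()`). Two consequences are
deliberate:

* normalization is scale-invariant, so plate-reader gain does not matter;
* viabilities above 1 are *kept*. Drug-induced increases in metabolic rate
  are a real phenotype in some resistant lines, not an artifact to clip. A
  configurable cap (`assemble_combination_grid(cap = 2)`) guards only
  against gross outliers.

Combination matrices are 7×7: each axis is a zero dose plus six three-fold
dilutions from the axis top dose (`build_combination_axis()`, default tops
0.03 µM for the backbone, 1 µM for partners). Embedding the zero dose means
the single-agent margins are measured on the same plate and at the same
passage as the combinations — the Bliss calculation below needs margins at
exactly the matched doses. An `all_nonzero` switch supports layouts whose
margins come from separate series.

## Single-agent dose–response

The four-parameter Hill model
$$v(c) = E_\infty + \frac{E_0 - E_\infty}{1 + (c/\mathrm{IC}_{50})^{h}}$$
is fitted by least squares with a deterministic multi-start bounded
quasi-Newton optimizer (15 starts over a grid of initial midpoints and
slopes; convergence tolerance $10^{-8}$ on the mean squared error, at most
5000 iterations per start). $E_0$ is left free near 1 ($[0.5, 1.5]$) rather
than pinned, because normalized data can sit slightly off 1 at zero dose;
$E_\infty \in [0, 1.2]$; $h \in [0.1, 10]$.

**Censoring.** Inhibition is measured against the no-drug control
(viability 1), not against the fitted $E_0$. If the fitted curve never drops
below viability 0.5 anywhere in the tested range, the IC50 is not
identified, only bounded: the fit is flagged `censored` and reports
$\mathrm{IC}_{50} \ge \text{max\_conc}$. This inequality propagates: a
censored agent contributes its bound to any Combination Index, which is then
itself only a lower bound (see below).

**AUC.** `compute_auc()` integrates viability over log10 dose by the
trapezoid rule and divides by the log-dose span, so a flat no-effect curve
scores exactly 1 and complete kill 0, independent of the dose range. This
makes AUCs comparable across series with different ranges and puts the
"no drug effect" reference at a fixed value.

**Cohort classification.** A line is called sensitive when its IC50 is
below 20% of the cohort median IC50. The median is computed over uncensored
IC50s only — censored bounds would inflate it — and censored lines are
labelled resistant outright, since their bound exceeds any threshold below
the top dose.

## The combination-surface model

Parametric response-surface models (multidimensional logistic) are too rigid
for measured combination surfaces, which can be non-monotone and
plateau-ridden. We therefore model the 7×7 surface non-parametrically with
an exact Gaussian process:

* **Inputs** are $\log_{10}(\text{dose} + \delta)$ per axis, where the
  pseudo-dose $\delta$ defaults to one tenth of the smallest nonzero dose on
  that axis. Zero doses need a finite log coordinate; $\delta$ an order of
  magnitude below the measured range keeps the zero-dose point separated
  from, but commensurate with, the dilution series.
* **Kernel**: squared-exponential with a separate length-scale per axis plus
  independent Gaussian noise; constant prior mean at the average observed
  viability. With 49 observations, exact inference is trivially cheap, so
  hyperparameters maximize the exact log marginal likelihood (to which a
  variational evidence bound collapses in the exact setting) by L-BFGS-B
  with analytic gradients from six deterministic starts; the optimum is
  always at least as good as every start.
* **Degenerate grids** (constant viability) are detected and fitted with
  near-zero signal variance rather than letting the optimizer wander; the
  posterior mean is then the constant, and the surface is flagged.
* **Prediction is confined to the measured dose box.** The GP is an
  interpolator here; queries beyond the tested ranges are refused rather
  than extrapolated.

Iso-effect contours (the dose pairs achieving a target inhibition on the
posterior mean) are traced by bisection along 50 rays from the dose origin
to the far edges of the box, to an inhibition tolerance of $10^{-3}$. If the
surface's maximum inhibition over the box is below the requested level, the
contour is reported as *not reached* — and, downstream, no Combination Index
is computed at that level. A GP posterior mean need not be monotone along a
ray; the tracer takes the first crossing, which for the effect levels used
here (0.25–0.75) is the biologically relevant one.

## Synergy scores

**Combination Index.** At effect level $xx$,
$$\mathrm{CI} = \frac{C_A}{\mathrm{IC}_{xx,A}} + \frac{C_B}{\mathrm{IC}_{xx,B}},$$
with $(C_A, C_B)$ a combination dose pair on the $xx\%$ iso-effect contour
and $\mathrm{IC}_{xx}$ each single agent's dose for that effect, inverted
from its Hill fit. CI < 1 is synergy (less drug needed together than
dose-equivalence predicts), 1 additivity, > 1 antagonism. The two-term
(mutually exclusive) form is used as printed in the Chou–Talalay literature;
no cross-term. When a single agent is censored, its bound
$\text{max\_conc}$ is substituted, making the CI a *lower bound*; such
values are flagged and excluded from optimal-regimen selection, a
conservative choice — a bound cannot win a minimum it might not deserve.

The **optimal regimen** is the dose pair with the smallest fully-computed CI
over the searched effect levels ({0.25, 0.5, 0.75} by default — the paper
trail for any specific screen should state its own levels), ties broken by
the smallest total concentration: when two regimens are equally synergistic,
prefer less drug.

**Bliss beta.** With margin inhibitions $f_A(i)$, $f_B(j)$ read from the
zero-dose row/column, Bliss independence predicts combination inhibition
$e_{ij} = 1 - (1 - f_A(i))(1 - f_B(j))$. Beta is the least-squares slope
through the origin of observed vs expected inhibition over the 36 interior
cells: $\beta = \sum o_{ij} e_{ij} / \sum e_{ij}^2$. This is the simplest
estimator consistent with the conventional calibration — exactly 1 on data
generated under Bliss independence, $1 + s$ on surfaces whose combination
inhibition is proportionally $(1+s)\times$ Bliss (uncapped), below 1 for
antagonism. Other beta definitions exist in screening software; ours is
stated here precisely so results are interpretable.

Synergy raises beta and lowers CI, so across a panel the two scores should
be negatively rank-correlated; `correlate_synergy_metrics()` computes the
Spearman rho (average ranks on ties).

## RPPA differential affinity

Reverse-phase protein array matrices arrive as normalized log2 values with
a per-antibody validation status. Analyses use *validated* antibodies only
("use with caution" antibodies are dropped by `filter_validated()`).

Drug-vs-vehicle comparisons within a stratum (a timepoint, a sensitivity
class, or both) use an empirical-Bayes moderated t-test: per-antibody
pooled variances $s_g^2$ (d residual df) are shrunk toward a common prior
$(d_0, s_0^2)$ estimated by moment matching of the $\log s_g^2$
distribution against a scaled inverse-chi-square model
($d_0$ from the trigamma inverse of the excess log-variance spread):
$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$
on $d + d_0$ df. Two boundary conventions: `prior_df = 0` disables
shrinkage and reproduces the ordinary two-sample t exactly; when the
observed variances show no excess spread beyond chi-square sampling noise,
the prior df is infinite and the common variance is the plain mean of the
$s_g^2$ — so identical sample variances shrink to themselves. Significance
is controlled at FDR < 0.05 by Benjamini–Hochberg. Samples are treated as
unpaired by default (`paired = TRUE` pairs drug/vehicle by cell line) —
pairing is a design fact the metadata must justify, not a default
assumption.

`set_comparison()` intersects the significant sets across strata per
direction of change, the tabular equivalent of the familiar two-way Venn
diagrams (early vs late timepoint, sensitive vs resistant).

## Xenograft summaries

Tumor volume uses the caliper ellipsoid formula $V = L W^2 / 2$ with the
convention $W \le L$ (violations are swapped with a warning, not dropped).
Group trajectories are summarized per day over the animals measured that
day — animals removed mid-study shrink $n$ from that day on, with no
imputation, matching how changing cohort sizes are reported in practice.
Endpoint comparisons are equal-variance Student's t-tests by default (the
convention of the graphing software used in such studies), with a Welch
option.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth
(`generator_spec()` + `gen_*()`), and the defaults *are* the study
conditions the package is tested under:

* 13-point, three-fold single-agent series from 10 µM; 7×7 combination
  grids on a 0.03 µM backbone axis × 1 µM partner axis, zero dose included;
* additive Gaussian viability noise, SD 0.05, truncated at 0 — absorbance
  noise after normalization is approximately additive on the viability
  scale at this magnitude;
* combination surfaces generated exactly under Bliss independence
  ($v_{ij} = v_A(i)\, v_B(j)$), exactly under Loewe additivity (the effect
  at each dose pair solved from $d_A/D_A(E) + d_B/D_B(E) = 1$ by bisection,
  tolerance $10^{-8}$, ≤ 200 iterations — there is no closed form for
  unequal slopes), or with a controlled synergy multiplier applied to the
  interior cells only (margins are single agents and must stay at their
  Hill response);
* RPPA: 1000 antibodies × (2 classes × 2 treatments × 2 timepoints × 3
  samples), planted effects of 1 log2 unit on 50 antibodies at noise SD
  0.25 — effect sizes and replication typical of RPPA screening contrasts;
* growth curves: exponential from 350 mm³ (the enrollment volume) at
  0.05/day, treatment multiplier 0.28 on the volume after treatment start,
  5% log-normal measurement noise, vehicle n = 8 vs treated n = 6.

Noise-free settings make oracle round trips exact: a Bliss-generated grid
has beta 1 to machine precision; a Loewe sham self-combination (a drug
paired with itself) must give CI = 1 along every contour, which exercises
the whole Hill → GP → contour → CI chain against dose additivity as an
internal consistency oracle.

What the generators do **not** emulate: plate spatial artifacts (edge
effects, drift), passage-to-passage drug-response variation, RPPA
antibody-specific dynamic ranges, or tumor regression kinetics beyond a
constant multiplier. Passing tests on synthetic data therefore demonstrate
the *statistical machinery* — estimator calibration, censoring logic, FDR
control — not robustness to those real-data failure modes.

## Numerical choices and problem sizes

All optimizations are deterministic multi-start local searches; no
stochastic optimizer is used anywhere, so results are bit-reproducible given
the input. Kernel matrices get a $10^{-10}$ diagonal jitter. The test suite
exercises parameter recovery at 100 synthetic curves, calibration sweeps at
20–25 seeded replicates, and GP length-scale recovery at 12 replicates —
sizes chosen so the whole suite documents the estimators' behavior while
running in well under a minute on a laptop core; the acceptance script's
reference grid is a single noise-free 7×7 surface.

## Known limitations

* The Hill inverse used for $\mathrm{IC}_{xx}$ extrapolates beyond the
  measured range for uncensored fits whose asymptote sits near the target
  viability; CI values at extreme effect levels inherit that uncertainty.
* The GP posterior mean can over-smooth very steep surfaces at 7×7
  resolution, biasing contour doses by a few percent near the box edges.
* Bliss beta is a single global slope; a combination that is synergistic in
  one dose region and antagonistic in another averages toward 1. The
  minimum-CI regimen view is the complement that localizes synergy.
* The moderated t assumes exchangeable antibodies and independent samples;
  correlated antibodies (shared pathways) make the FDR nominal rather than
  exact.
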