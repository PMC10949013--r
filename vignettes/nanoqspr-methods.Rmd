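---
title: "Two-stage periodic-table QSPR for metal-oxide nanoparticles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage periodic-table QSPR for metal-oxide nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoqspr)
```

## The modeling problem

Metal-oxide nanoparticles (MeOx NPs) damage cell membranes through surface
chemistry that is expensive to characterize experimentally. Two quantities
organize the problem: the **zeta potential** (the electrostatic potential at
the particle's slipping plane, in mV — a proxy for surface charge and
colloidal stability), and a **cell-damage** response measured as a
continuous score from a propidium-iodide uptake assay over a dose x
exposure-time design.

`nanoqspr` implements a two-stage regression analysis on *periodic-table
descriptors*: features computed from nothing but the chemical formula and a
table of element constants, with no 3-D structure, size, or image input.

1. **Stage 1 (zeta model).** A PLS model with one latent variable links
   three descriptors — the metal oxidation number `chi_ox`, the
   formula-unit core-environment descriptor `tot_metal_alpha`, and the
   tabulated valence electron potential `vep` — to measured zeta potential
   over a small oxide panel (18 oxides, 13 train / 5 test).
2. **Imputation.** The damage dataset has no measured zeta, so stage-1
   predictions are *imputed* as a descriptor — a model embedded within a
   model, standard practice for filling sparse endpoints in QSAR.
3. **Stage 2 (damage model).** A PLS model with seven latent variables on
   eight descriptors (`sum_chi_per_nO`, `sq_sum_epsilon_N`, `d1_metal`,
   `metal_alpha`, exposure time, imputed zeta, `electrons_active_m`,
   `valence`) predicts the damage score over 132 design points.

Everything downstream of the descriptors — validation metrics, the
applicability domain, read-across — treats the models as ordinary linear
predictors with a raw-scale intercept and coefficient vector.

## Descriptor calculus and its conventions

Let the oxide be $\mathrm{M}_{n_M}\mathrm{O}_{n_O}$ with metal atomic
number $Z$.

* `chi_ox` $= 2 n_O / n_M$ — stoichiometric charge balance against
  O$^{2-}$. Mixed-valence oxides (Fe$_3$O$_4$) get the fractional average
  8/3; per-site oxidation states are deliberately not resolved, which
  matches the printed values for WO$_3$ (6) and NiO (2).
* `metal_alpha` $= \frac{Z - Z_v}{Z_v}\cdot\frac{1}{PN}$. Two conventions
  had to be fixed from printed values, and the calibration is worth
  recording: with $Z_v$ = electrons in the *highest principal shell of the
  neutral atom* (W 2, Al 3, Yb 2, Sn 4) and $PN$ = *period minus one*, all
  four published values (W 7.2, Al 1.67, Yb 6.8/atom, Sn 2.875) are
  reproduced exactly. No other simple combination of
  $Z_v \in \{$outer shell, group valence$\}$ and
  $PN \in \{$period, period$-1\}$ does.
* `tot_metal_alpha` $= n_M \cdot$ `metal_alpha`; `d1_metal` $= n_M$;
  `electrons_active_m` $= Z$ (not scaled by $n_M$).
* `sum_chi_per_nO` $= n_M \chi_M / n_O$ with $\chi$ the Pauling scale.
* `valence` = bonding valence-electron count: group number (s+d) for
  transition metals, 2 for filled-d group 12 (so Mn 7 but Zn 2), s+p count
  for main-group metals. The oxidation-state reading was rejected because
  MnO$_3$'s printed value (7) equals the electron count, not the state (6).
* `vep` and `epsilon` are **tabulated, not recomputed**. The
  valence-electron-potential formula $k\,n/r$ ($k = 14.399$ eV·Å, $r$ a
  Shannon radius) reproduces the literature value for Co (38, Co$^{2+}$)
  but the literature Mn value (220) only under Mn$^{7+}$ — the
  oxidation-state convention is internally inconsistent, so the table
  carries the published numbers verbatim and seeds the rest from common
  cation states. Similarly the "electronegativity count" $\varepsilon$
  behind `sq_sum_epsilon_N` $= ((\varepsilon_M n_M + \varepsilon_O n_O)/
  (n_M + n_O))^2$ is pinned only at CuO (9.93) and Sb$_2$O$_3$ (0.018);
  those two ship as per-oxide overrides, $\varepsilon_O$ is fixed at 0,
  the Cu and Sb entries are back-solved from the pinned values, and every
  other metal carries a *synthetic placeholder* (its Pauling χ) that is
  fine for simulation but is not a literature constant.

Dose (µg/mL) is carried as metadata but is **not** a damage-model
descriptor: the published equation has a time term and no dose term, and
the tests verify predictions are dose-invariant.

## Model fitting

`fit_mlr` is QR-based least squares on raw descriptors; rank deficiency is
an error that names the collinear columns. `fit_pls` is single-response
NIPALS on autoscaled X and centered y with deflation on X; for one
response each component is a closed-form power step, so the nominal
tolerance (1e-10) never iterates. The fitted object stores the equivalent
raw-scale regression vector
$\beta = W(P^\top W)^{-1}q \,/\, s_x$, which makes the identity
PLS($p$ LVs) ≡ OLS testable and keeps prediction independent of the
internal scaling. `n_latent` above the design rank is capped with a
warning.

Published coefficients are treated as raw-scale (the equations are written
in measurement units) and frozen verbatim in `published_model()`.

## Validation

* $R^2 = 1 - SS_{res}/SS_{tot}$; $Q^2_{LOO} = 1 - PRESS/SS_{tot}$ with the
  feature set held fixed across folds (no re-selection).
* External: $Q^2_{F1}$ normalizes by deviation from the *training* mean,
  $Q^2_{F2}$ by the *test* mean; $Q^2_{F1} \ge Q^2_{F2}$ always.
* Roy's $\bar{r^2_m}, \Delta r^2_m$: computed on min-max scaled series
  (the metric's standard recommendation; `scale = FALSE` gives the raw
  variant), with the radicand clamped at 0 under a warning when numerical
  noise pushes $r^2 < r^2_0$.
* $F = (R^2/p)/((1-R^2)/(n-p-1))$. For PLS, $p$ = latent variables is the
  headline convention (it reproduces the published single-LV zeta-model
  F of 44.2 within rounding; descriptor-count $p$ is also computable) and
  the choice is recorded in the report.
* Y-randomization shuffles the response under a seed and reports the
  permuted-$R^2$ distribution and exceedance fraction.
* The Golbraikh–Tropsha gate is the boolean $R^2 > 0.6 \wedge Q^2 > 0.5$.

**Applicability domain.** Leverages are hat values of the training design
(descriptors + intercept; for PLS the descriptors, not the scores, span
the domain — that is what makes the damage-model geometry $p = 9$,
$n = 111$, $h^* = 3p/n = 0.2432$). Training points get LOO residuals via
the exact OLS shortcut $e_i/(1-h_i)$, standardized by the SD of the LOO
residuals; evaluation points get plain residuals on the same scale.
$|r_{std}| > 3$ flags response outliers, $h > h^*$ leverage outliers.

## Read-across

The reference tool's internals are unpublished; the neighbor rule here is
the simplest one consistent with its four hyperparameters, and is
documented as a reimplementation: autoscale descriptors by training
statistics; a training point is an eligible neighbor if its Euclidean
distance is at most `distance_threshold` (interpreted in those scaled
units) *and* its similarity is at least `similarity_threshold`; keep the
`n_neighbors` most similar (default 10); predict the similarity-weighted
mean. Similarities: ED $1/(1+d)$, GK $\exp(-d^2/2\sigma^2)$, LK
$\exp(-\gamma d)$ (defaults $\sigma=\gamma=1.75$, the published tuned
values). Queries with no eligible neighbor fall back to the training mean
and are flagged and counted, since they dilute external metrics.
`optimize_hyperparams` reproduces the published tuning protocol: a seeded
70/30 sub-split of the training set and an exhaustive grid search
maximizing $Q^2_{F1}$, ties broken by grid order.

## The synthetic world

The generator emulates the *shape and stated statistics* of the two study
tables, not their actual rows (which have no public accession):

* element constants are real (a curated pool of 26 formulas over 23
  metals), so the descriptor
  collinearity structure resembles real data rather than white noise;
* dataset I: 18 oxides sampled from the pool, zeta = stage-1 equation +
  $N(0, \sigma_\zeta^2)$;
* dataset II: the oxides x {50,100,150,200} µg/mL x 1–7 h design
  subsampled to 132 rows, damage = stage-2 equation (with equation-derived
  zeta) + $N(0, 0.361^2)$ — 0.361 is the published training standard
  error;
* $\sigma_\zeta$ = 9 mV, calibrated once from stated quantities: the
  stage-1 linear predictor has SD 18.3 mV over the pool and the published
  training $R^2$ of 0.80 implies noise = 0.5 × signal SD;
* dose is generated but never used, so tests can confirm the pipeline
  ignores it;
* the train/test split is a seeded 7:3 permutation (the published
  division tool's algorithm is unspecified), and `set_label` from a file
  always takes precedence.

What a green synthetic test establishes: the machinery — descriptor
calculus, fitting, imputation, validation, domain, read-across — is
correct and deterministic, and the stated noise level yields refit
quality bracketing the published one (implied damage-model $R^2 \approx
0.75$ at the published noise, inside the published 0.62's plausibility
envelope). What it does not establish: reproduction of the measured
tables, medium effects on zeta (dataset I was measured in 20% fetal
bovine serum medium, dataset II's solvent differs — recorded, not
reconciled), or the real spectrum of the damage endpoint, whose units and
transform are never stated and are treated as an abstract continuous
response. One visible consequence: with the published zeta coefficient
(0.00057/mV) the synthetic ablation drop in $R^2$ is real but small
(~0.002–0.01), whereas the reported drop on the measured data (0.62 to
0.47) is much larger — the synthetic world only pins the *direction* of
the ablation effect.

## Numerical choices and degenerate inputs

* Stepwise selection treats RSS improvements below $10^{-12}\,SS_{tot}$
  as zero (noise-free designs would otherwise produce unbounded partial
  F), and breaks enter/remove oscillation after 100 cycles.
* `fit_mlr` permits exact interpolation ($n = p + 1$: a line through two
  points) but refuses underdetermined designs.
* Descriptor errors aggregate per row before failing, so a bad formula in
  a 132-row table is reported with its row index and message.
* All generators and the pipeline are pure functions of their seed;
  output files are written with pinned formatting and are byte-identical
  across reruns under one seed.
* A robust data-quality screen (|value − median| > 3 MAD) flags
  implausible entries (the literature contains a 2130 mV zeta value,
  presumably a typo) without altering them.

## Known limitations

* $\varepsilon$ and `vep` are lookups with two-point literature anchors;
  descriptor values for unanchored metals are internally consistent but
  not literature-validated, which would dominate any attempt to reproduce
  measured-data coefficients exactly.
* The damage-model training size is printed inconsistently in the source
  material (110 vs 111); the package records whatever the data contain.
* The prediction-reliability triage of the original workflow is not
  reproduced (its scoring rules are undisclosed), and no figures are
  rendered — Williams and read-across data are exported as CSV for
  external plotting.
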