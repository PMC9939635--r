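---
title: "Methods: multi-media metal mixtures and brain-network efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-media metal mixtures and brain-network efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Adolescents living near ferro-manganese industry are exposed to a *mixture*
of neurotoxic metals — manganese, lead, chromium and copper — and each metal
can be measured in several biological media (blood, urine, hair, saliva)
that reflect different toxicokinetic compartments. No single biomarker
captures total body burden. At the same time, resting-state fMRI summarises
how efficiently the brain integrates information through two graph metrics
on the functional connectome: global efficiency (GE) and local efficiency
(LE), both scaled to [0, 1].

`mmbwqs` implements the full analysis chain linking these two sides:

1. **Pre-whitening** of atlas-extracted ROI time series (two-step GLM with
   AR(1) removal and confound regression).
2. **Connectome construction** and weighted global/local efficiency.
3. **Hierarchical weighted quantile sum (WQS) regression**: a level-1
   "multi-media biomarker" (MMB) index per metal across its four media,
   then a level-2 mixture index across the four metal MMBs, with
   sign-constrained weights, bootstrap weight ensembles and
   repeated-holdout inference, adjusted for age and sex.

Because no cohort data are deposited, the package also ships a synthetic
cohort generator with fully recorded ground truth; every stage of the
pipeline is validated against it.

## Pre-whitening model

Each ROI's time series \(x_t\) is assumed to carry nuisance structure from
head motion and physiological signals plus serial correlation well
approximated by an AR(1) process. `preprocess_subject()` follows a two-step
generalized linear model:

* **Step 1.** Each ROI column is residualized on an intercept and the six
  rigid-body motion parameters. The residuals give a per-ROI lag-1
  autocorrelation \(\hat\rho_j\) (`estimate_ar1()`), and the *raw* data are
  whitened as \(x^*_t = x_t - \hat\rho_j x_{t-1}\), dropping the first
  timepoint rather than back-forecasting it (the simplest exact contract).
* **Step 2.** The whitened series is residualized on an intercept, the six
  motion parameters, and the white-matter and CSF signals, with the
  regressors whitened by the *same* \(\hat\rho_j\) so the AR(1) model stays
  coherent within each ROI's regression. Motion therefore enters both
  steps; this double projection is harmless (projections are idempotent)
  and keeps the confound model of the second step complete.

The AR coefficient is estimated per ROI rather than globally because
regional autocorrelation in BOLD data is heterogeneous; on a true AR(1)
input the cleaned series has lag-1 autocorrelation 0 within sampling noise,
and the output is orthogonal to the whitened regressor span to machine
precision. No global signal regression is applied.

## Connectome and efficiency metrics

The edge definition is deliberately simple: Pearson correlation between
cleaned ROI series, negative values truncated to zero and the diagonal
zeroed. Truncation keeps the conventional inverse-weight path length
\(\ell_{ij} = 1/w_{ij}\) well defined; an optional proportional density
threshold (`correlation_graph(density = )`) is provided for sensitivity
analyses but is off by default, since no thresholding rule can be claimed
canonical.

With additive path lengths \(1/w\) (the Brain Connectivity Toolbox
convention) and shortest-path distances \(d_{ij}\) (Dijkstra, via igraph):

* **Global efficiency** is the mean over ordered node pairs of
  \(1/d_{ij}\), with unreachable pairs contributing 0 — this keeps GE in
  [0, 1] and monotone in edge weights. GE is exactly 1 on a complete
  unit-weight graph and 0 on an edgeless graph.
* **Local efficiency** of node \(i\) is the global efficiency of the
  subgraph induced by its direct neighbours with \(i\) removed; nodes with
  fewer than two neighbours score 0. The per-subject scalar LE is the
  unweighted mean over all nodes.

Both are verified against an independent brute-force Floyd–Warshall
implementation on exhaustively sampled small graphs (tolerance 1e-12).

## WQS regression and the exact solver

A WQS model regresses the outcome on a single index \(\sum_i w_i q_i\) of
decile-scored components \(q_i \in \{0,\dots,9\}\), with \(w\) on the
probability simplex and the index coefficient \(\beta_1\) constrained to a
direction (negative here: metals are not expected to improve efficiency).
Deciling uses average ranks for ties — deterministic and invariant under
monotone transforms — and maps constant columns to zero.

With an identity link this estimation problem has special structure that
the package exploits: substituting \(\theta = \beta_1 w\) turns

\[
\min_{w \in \Delta,\ \beta_1 \le 0,\ b}
  \lVert y - Xb - \beta_1 Qw \rVert^2
\quad\text{into}\quad
\min_{\theta \le 0,\ b} \lVert y - Xb - Q\theta \rVert^2 ,
\]

an exact reparameterization (\(\beta_1 = \sum_i \theta_i\),
\(w = \theta/\beta_1\), uniform if \(\beta_1 = 0\)). The right-hand side is
sign-constrained least squares — a convex quadratic program. After
profiling out the unconstrained covariate block (Frisch–Waugh), the global
optimum is found *exactly* by enumerating candidate supports (for
\(p \le 8\) components; the optimum restricted to its support is the
unconstrained least-squares solution there and is sign-feasible), with
Lawson–Hanson NNLS as the fallback for larger \(p\). This makes every fit
deterministic, removes any dependence on starting values or convergence
tolerances, and is fast enough to run the full 50-bootstrap ×
100-holdout lattice in seconds. The solver is validated against a
0.01-step dense simplex grid search on 2–3 component problems
(objective gap < 1e-6).

## Repeated-holdout inference

`fit_wqs_repeated()` repeats, `n_holdouts = 100` times: randomly split
subjects 60/40 into training and validation (the split fraction follows
common repeated-holdout WQS practice; the analysis that motivated this
package states the split but not the fraction); fit the sign-constrained
model on `n_boot = 50` bootstrap resamples of the training part and average
the 50 weight vectors (unweighted — sign-constrained fits cannot flip
direction, so no significance filter is applied); then compute the index on
the validation part with the averaged weights and fit an *unconstrained*
linear model of the outcome on index, age and sex. The mean of the 100
validation coefficients is the point estimate; their 2.5th/97.5th
percentiles form the 95% CI; weight distributions are summarised by their
mean and 10/25/50/75/90th percentiles.

The validation regression is left unconstrained on purpose: truncating
positive validation coefficients at zero would pin the CI's upper bound at
0 under a null effect and destroy the interval's calibration. With a real
negative effect the validation coefficients are negative anyway. Null
calibration is checked empirically in the test suite (coverage of 0 across
100 simulated null cohorts must fall in the binomial 89–99 band).

Components whose mean weight strictly exceeds \(1/p\) (the uninformative
uniform weight) are flagged by `significant_components()`.

## The hierarchical MMB procedure

* **Level 1** (`fit_level1_mmb()`): for one metal, the four media
  concentrations are decile-scored (censored values first imputed as
  LOD/\(\sqrt 2\), the standard censored-analyte convention; the audit
  trail of the flag is preserved) and fed through the repeated-holdout WQS.
  The per-subject MMB score is the decile matrix times the holdout-mean
  media weights — kept on the 0–9 quantile scale so level 1 and level 2
  operate on the same footing.
* **Level 2** (`fit_level2_mixture()`): the four MMB scores are
  *re-deciled* (all exposures enter the models as deciles) and the
  repeated-holdout WQS is run across metals, adjusted for age and sex.

Note the scale convention: the fitted \(\beta_1\) is per decile unit of the
index (which spans 0–9), while the generator's injected effect is defined
per unit of the [0, 1]-scaled index; sign and inference are unaffected.

`run_pipeline()` performs complete-case analysis (subjects missing any of
the 16 components, a covariate or an outcome are dropped, with counts
reported), computes graph metrics first if ROI time series are supplied,
and runs both outcomes (GE, LE) with identical derived seeds for
comparability. Sex is coded 0/1 and age entered in years, both
untransformed. All randomness flows from one root seed through documented
stream splitting, making every report bit-reproducible.

## What the synthetic generator emulates

`generate_cohort()` draws the 16 biomarkers log-normally with the
geometric means, geometric SDs and LODs of the shipped defaults
(`exposure_defaults()`, the printed summary table of the emulated cohort);
media of one metal share a single latent Gaussian factor giving a common
log-scale correlation `cross_media_rho` (default 0.3 — the cohort's
cross-media correlation table is not public, so this is a free moderate
value). Values below the LOD are *flagged* but stored as drawn: the
generator never destroys information, which lets tests compare imputation
policies against truth. Covariates follow the emulated cohort (age uniform
15–25, sex Bernoulli 0.53; n = 193 by default).

The latent burden of a subject is built exactly the way the estimator sees
the world — level-1-weighted decile scores, re-deciled and combined with
level-2 weights, scaled to [0, 1] — with default truth weights echoing the
reported contribution pattern (urine-heavy media weights; metal weights
Mn .24, Pb .29, Cr .29, Cu .18) and default effects
\(\beta_{GE} = -0.076\), \(\beta_{LE} = -0.048\), noise SD 0.02
(intercepts 0.65/0.78 place outcomes in the plausible efficiency range
and keep the noiseless model inside [0, 1], making the injected effect
exactly recoverable).

Two outcome routes exist:

* **Direct mode** (`generate_direct_outcomes()`): efficiency = linear
  model in burden + covariates + noise. Used for statistical recovery and
  calibration tests, where the estimand is known exactly.
* **Time-series mode** (`generate_timeseries()`): per subject, a
  stationary multivariate AR(1) series (temporal \(\phi = 0.3\)) whose
  innovation correlation has `n_modules = 6` blocks — within-module
  correlation 0.65, between-module coupling
  \(0.45 - 0.25 \times\) burden. The effect is injected into
  *between-module* coupling only, because that is what network
  integration (GE) measures. Synthetic motion/WM/CSF signals
  (AR(1), \(\phi = 0.85\)) are mixed into the ROI data with random
  coefficients (SD 0.4) so confound regression is genuinely exercised.
  Defaults are 111 ROIs and 600 timepoints (10 min at TR = 1 s).

What the generator does **not** emulate: voxel-level images, spatially
structured or spike-like motion artifacts, scanner drift and physiological
noise spectra, non-log-normal biomarker tails, metal-specific cross-media
correlation structure, and any nonlinearity or interaction in the
exposure–outcome relation. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated model —
not that the model captures every feature of real cohort data.

## Numerical choices and degenerate inputs

* Constrained solver: exact support enumeration, feasibility tolerance
  1e-10 on signs; singular support systems are skipped (the zero solution
  is always a candidate). Weight vectors sum to 1 within 1e-8 everywhere.
* Deciling: `floor((rank - 1) * 10 / n)` with average ranks for ties; bins
  differ by at most one count when values are distinct.
* Whitening drops the first timepoint; zero-variance ROI columns,
  rank-deficient designs and nonstationary AR estimates are hard errors
  naming the offending column.
* Unreachable node pairs contribute zero efficiency; nodes with < 2
  neighbours have LE 0; single-node graphs are errors.
* Report JSON is written at full precision (`digits = NA`) and
  round-trips losslessly.

## Problem sizes used in the test suite

Unit tests run at reduced scale (tens to hundreds of subjects, 5–20
bootstraps/holdouts) to stay fast; the acceptance-style checks run the
study-scale settings: 50 bootstraps × 100 holdouts, n = 500 recovery over
20 seeded cohorts, 100-cohort null calibration at n = 200, and
100,000-subject generator-fidelity draws. These sizes are the package's
validation design, chosen so each check has the statistical resolution its
tolerance needs.

## Known limitations

* The edge definition (truncated Pearson correlation, no thresholding) is
  one reasonable choice among several; the density-threshold option exists
  precisely because the canonical choice is unknowable.
* Linear, additive exposure effects only — no interactions, no nonlinear
  dose–response, matching the WQS framework's assumptions.
* The level-1/level-2 hierarchy reuses the same subjects twice; the
  repeated-holdout split mitigates but does not eliminate the attendant
  optimism, a known property of hierarchical WQS.
* Cross-media correlation is exchangeable within metal; real
  toxicokinetics are richer.
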