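---
title: "Simulation-based power analysis for ROI spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for ROI spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roipower)
```

# Overview

`roipower` estimates statistical power for GeoMx-style region-of-illumination
(ROI) experiments that compare gene expression between patient groups within
tissue compartments.  The workflow has five stages, each usable on its own:

1. **Synthetic reference data** — Visium-like spot grids with planted
   compartments, and a bulk RNA-seq cohort with planted gene-set effects.
2. **Endpoint discovery** — normalization, a covariate-adjusted candidate
   screen in the bulk cohort, gene-set summary scores, score co-localization,
   and percentile segmentation of spots into compartments.
3. **Spike-in calibration** — translating a bulk log2 fold change into a
   compartment-level spike fraction via a calibration curve.
4. **ROI simulation** — aggregating compartment spots into synthetic ROIs and
   synthetic patients, with optional quality-control dropout.
5. **Power engine** — negative binomial mixed models over a grid of design
   conditions.

This vignette records the statistical model, the main tunable parameters, the
numerical choices, and the design decisions taken where the design was
genuinely open.

# The count model

For ROI counts $y_{ij}$ of one gene (patient $j$, ROI $i$):

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \theta), \qquad
\log \mu_{ij} = \log L_{ij} + \beta_0 + \beta_1\,\mathrm{group}_j + u_j,
\qquad u_j \sim N(0, \sigma^2).$$

* $L_{ij}$ is the **TMM effective library size** (raw library size times the
  trimmed-mean-of-M-values factor, computed with edgeR), entering as a fixed
  offset on the natural-log scale.  Composite gene-set sum rows are excluded
  from the library-size computation.
* $\theta$ is the gene-wise NB size (larger = closer to Poisson), estimated
  per fit, not shared across genes.
* $u_j$ absorbs within-patient correlation of repeated ROIs.
* The reported effect is $\beta_1 / \ln 2$, a log2 fold change.

The marginal likelihood integrates $u_j$ out per patient with **adaptive
Gauss–Hermite quadrature** (AGQ): nodes are centred at each patient's
conditional mode (found by a per-patient Newton iteration, warm-started
across likelihood evaluations) and scaled by the local curvature.  Fifteen
nodes are the default; the likelihood changes by less than $10^{-4}$ when
increased to 25 on datasets of the default scale, and AGQ agrees with a
dense trapezoid integration oracle (`marginal_loglik_oracle()`) to within
$10^{-3}$ on small instances — both are asserted in the test suite.

Inference on $\beta_1$ is by Wald test (coefficient over standard error from
the numerical Hessian) or likelihood-ratio test against the nested model
without the group term.  The default level is $\alpha = 0.025$: a family
level of 0.05 split over two co-primary endpoints.  A transcriptome-wide
analysis over roughly 2000 reliably detected genes would use
`alpha_adjust(0.05, 2, 2000)` = 1.25e-05.

## Numerical choices

* Parameters are optimized as $(\beta_0, \beta_1, \log\theta, \log\sigma)$
  by L-BFGS-B with box constraints $\log\theta \in [-7, 12]$,
  $\log\sigma \in [-8, 3]$, falling back to Nelder-Mead (reltol $10^{-10}$)
  if the gradient-based pass does not report convergence.  Start values come
  from the fixed-effects NB GLM fit.
* The marginal likelihood is flat in $\log\sigma$ as $\sigma \to 0$.  A
  solution with $\sigma < 10^{-3}$ whose likelihood the fixed-effects GLM
  matches (within $10^{-4}$) is treated as a boundary fit: $\sigma$ is set
  to 0 and the model is refitted as a GLM.  This mirrors the analytic fact
  that the marginal model degenerates continuously to the GLM.
* The LRT refits the full model from the null optimum whenever the first
  pass lands below it, so the statistic is non-negative on converged pairs.
* The NB GLM profiles $\theta$ by 1-D maximum likelihood (golden-section on
  $\log\theta$), with IRLS (`glm.fit` + `MASS::negative.binomial`) inside.
* Power is reported as rejections among *converged* repeats, with the
  convergence rate alongside; `run_config(count_nonconverged = TRUE)`
  switches to counting failures as non-rejections.

# Synthetic reference data

`generate_spot_dataset()` emulates the structure the downstream analysis
relies on, not liver histology:

* **Grid and compartments.**  Each sample is a `grid_rows x grid_cols` grid
  of 55 µm spots at 100 µm centre spacing.  A fibrotic-niche compartment
  (default 5% of spots, jittered ±10% per sample, i.e. within the 2.6–7.1%
  range seen across NAFLD-stage fibrotic tissue) and a hepatocyte
  compartment (default 65%, the lower range of literature estimates of
  hepatocyte volume fraction) are planted as contiguous blobs grown from
  random seeds on the 4-neighbour lattice; niche blobs are deliberately
  small (about 12 spots) because fibrotic septa are thin structures.
* **Counts.**  Gene $g$ in a spot of class $c$ is
  $\mathrm{NB}(L_s\,\rho_{gc}, \theta)$ with log-normal per-spot library
  sizes (default $\log L \sim N(\log 4000, 0.35^2)$) and class profiles
  $\rho$ normalized to sum to one.  The NB family is chosen to match the
  downstream fitted model; no generative claim beyond that is intended.
* **Marker structure.**  Hepatocyte and lipid-metabolism marker sets are
  elevated (default 4-fold) in hepatocyte spots and halved in the niche;
  ECM and mesenchyme sets are 8-fold up in the niche and 2-fold up in
  "other" tissue; cytoskeleton markers are niche-elevated.  The
  intermediate ECM level in "other" tissue is what makes the 80th ECM
  percentile fall above the hepatocyte compartment, so the percentile
  segmentation can separate all three classes.  Default set sizes are 44
  (lipid) and 89 (cytoskeleton), matching the bulk-screen set sizes, with
  background probes planted at or below a tenth of the median relative
  expression.
* **Exchangeability.**  No sample-level expression effect is planted, so
  spot profiles correlate no more strongly within a sample than between
  samples — the property that justifies assembling synthetic patients by
  randomly partitioning freshly drawn ROIs.

The generator does **not** emulate: spatial expression gradients beyond the
compartment blobs, cell-type mixtures within spots, sample-level batch
effects, or segment-area/nuclei covariates.  Passing tests therefore show
that the pipeline is correct and calibrated *under its own assumptions*;
they do not show that a particular real tissue meets those assumptions (in
particular real data may carry patient-level effects, which the random
intercept is there to absorb).

`generate_bulk_cohort()` draws 28 stable / 15 progressor / 15 regressor
subjects (defaults) with fibrosis stage F1–F4 and NAS 0–8 covariates, and
plants opposite-direction gene-set effects: a set with effect $d$ is scaled
$2^{d}$ in progressors and $2^{-d}$ in regressors (defaults: lipid $-0.42$,
cytoskeleton $+1.5$).  Expected relative expression is scaled by the
unmodified base total so the planted contrasts are exact on the log scale.

# Endpoint discovery

* `normalize_counts()` uses median-of-ratios size factors and
  $\log_2(\mathrm{count}/sf + 1)$.  This is a deliberately simple,
  depth-corrected log transform with the same semantics as regularized-log
  pipelines; for sparse spot matrices, where no gene may be expressed
  everywhere, `method = "libsize"` references total counts to their
  geometric mean instead.
* `candidate_gene_screen()` fits one OLS per gene with two group dummies
  (progressor, regressor vs stable) plus categorical fibrosis stage, and
  selects genes with opposite-sign contrasts and raw $p < 0.05$ in both —
  a hypothesis-generation filter, deliberately uncorrected.  One model with
  two contrasts (rather than two separate regressions) was chosen; with a
  shared stage adjustment the two parameterizations give identical
  contrasts.
* `kuppe_score()` averages normalized expression over a gene set, drops
  members correlating below 0.1 (Pearson, config-switchable to Spearman)
  with the initial average, and re-averages — exactly one
  filter-and-update cycle, not iterated to convergence.  Genes with
  undefined correlation (zero variance) are retained.
* `segment_spots()` thresholds per sample: niche = ECM $\ge$ P85 and
  hepatocyte score $\le$ P15; hepatocyte = hepatocyte $\ge$ P20 and ECM
  $\le$ P80.  Percentiles are computed *within* each sample (samples differ
  in depth and composition, and compartment fractions are reported per
  sample); linear-interpolation percentiles; ties at a threshold are
  included per the at-or-above wording.  If both scores are constant within
  a sample the niche conjunction is unsatisfiable and the niche is empty
  (with a warning, since an empty niche can also be a legitimate
  condition-dependent outcome).  Niche takes precedence over hepatocyte in
  the rare case both rules fire, keeping the label sets disjoint.

# Spike-in calibration

`apply_spike()` adds $r \times$ (per-sample class median of the gene's
unmodified counts) to every target-class spot.  Increments are rounded
half-up so count models receive integers; `integer_counts = FALSE`
preserves fractional spikes for sensitivity checks.  The median is always
taken on unmodified counts — the spike is not self-referential.

`build_calibration_curve()` sums all spots per sample into pseudobulk and,
for each $r$ on a grid (default 0 to 4 by 0.1), computes the log2 fold
change of spiked vs unmodified pseudobulk with a paired NB GLM (condition +
sample fixed effect, median-of-ratios offsets over all $2n$ columns,
profiled dispersion, Wald inference).  Because the spike touches a single
gene row, the pseudobulk update is computed incrementally.
`invert_calibration()` linearly interpolates between the bracketing grid
points, returning the smallest bracketing solution on non-monotone curves,
and refuses targets outside the observed range rather than extrapolating.
The bulk screen's standard-error band is carried in the curve as metadata;
matching is on the point estimate.

Because the hepatocyte compartment dominates bulk tissue while the niche is
a few percent of spots, equal bulk fold changes require far larger spike
fractions in the niche — the dilution effect that motivates calibrating at
the compartment level in the first place.

# ROI simulation

* `diameter_to_spot_count()`: captured material scales with area, so a
  $D$ µm ROI aggregates $\mathrm{round}((D/55)^2)$ spots — 2, 4 and 9 for
  80, 110 and 165 µm.  Rounding is half-up.
* `sample_rois()` grows a grid-adjacent same-sample patch from a random
  seed spot; when a thin compartment cannot host a contiguous patch of the
  requested size, the $k$ nearest same-class spots stand in.  Spots may be
  reused across ROIs and repeats: the reference spots are treated as a
  population that is resampled, not consumed.
* `assemble_dataset()` draws the control group from the unmodified pool and
  the spiked group from the spiked pool, then partitions each group's ROIs
  into patients with exactly `n_rois_per_patient` each.  The random
  partition (rather than a planted patient effect) is justified by the
  exchangeability of the reference spots; the fitted model still carries a
  random intercept so that the test is honest about within-patient
  correlation it cannot rule out.  Panel restriction keeps flagged panel
  members, background probes and always the endpoint gene.
* `apply_dropout()` removes a uniform random ROI subset, rejection-sampled
  so no patient loses all ROIs.

# Power engine

`run_condition()` derives one seed per repeat by hashing the master seed,
the condition fields and the repeat index (`derive_seed()`, a 31-bit
multiplicative string hash), so grid cells and repeats are independent and
order-invariant, and a dropout run with `n_remove = 0` reproduces the
nominal run exactly.  Each repeat assembles a dataset, computes TMM
effective library sizes on the panel genes, and tests the endpoint gene
with each requested method; additional methods can be plugged in as
functions `(y, group, patient, offset) -> list(p, lfc, converged)`.
Fold changes are summarized as median and quartiles over converged repeats.

# Problem sizes used in the tests

The packaged checks run on a reference-scale synthetic dataset of 5 samples
of 30 × 30 spots and 300 genes — large enough for every compartment to host
165 µm ROIs in every sample, small enough to keep the whole suite
desk-scale.  Type-I calibration uses 1000 repeats at 10 patients × 2 ROIs;
parameter recovery 500 simulated fits at 20 patients × 2 ROIs
($\sigma = 0.3$, $\theta = 5$, planted lfc 0.33); power monotonicity 200
repeats per cell at 4/8/16 patients; AGQ-vs-oracle equivalence 50 random
instances of at most 6 patients × 4 ROIs.  These sizes are the package's
own trade-off between Monte-Carlo error and runtime.

# Known limitations

* The NB GLMM assumes a single random intercept; crossed or nested random
  effects, zero inflation, and empirical-Bayes dispersion shrinkage across
  genes are out of scope.
* Calibration matches fold-change point estimates; propagating the bulk
  screen's uncertainty band through the inversion is left to the user (the
  band is exposed on the curve).
* The Wald test relies on the normal approximation to the profile score;
  with very few patients per group the likelihood-ratio test is the safer
  default, at roughly twice the computational cost.
* The generator's compartments are homogeneous: real compartment
  heterogeneity (gradients, mixed spots at boundaries) will make percentile
  segmentation noisier than it is here.
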