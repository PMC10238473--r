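# roipower

Simulation-based power analysis for NanoString GeoMx-style
region-of-illumination (ROI) group-comparison experiments, built on
spot-level spatial transcriptomics reference data.

## The problem

Planning a GeoMx experiment that compares gene expression between patient
groups inside specific tissue compartments (for liver fibrosis: the
fibrotic niche and the hepatocyte fraction) raises three questions that
standard power formulas do not answer:

1. **What effect size should be assumed?**  Candidate endpoints come from
   bulk RNA-seq cohorts, but a signal confined to a small compartment is
   *diluted* in bulk tissue — a bulk log2 fold change understates the
   compartment-level effect for a rare compartment.
2. **How do ROI size, ROIs per patient and patients per group trade off?**
   ROI counts are overdispersed and repeated ROIs within a patient are
   correlated.
3. **What happens when ROIs fail quality control?**

`roipower` answers all three by simulation.  Visium-like 55 µm spots serve
as a resampling population: segmented compartment spots are aggregated
into synthetic ROIs (2/4/9 spots mimic 80/110/165 µm diameters, since
captured material scales with area, i.e. quadratically in diameter),
assigned to synthetic patients, and tested per gene with a negative
binomial mixed model

```
  y_ij ~ NB(mu_ij, theta),   log mu_ij = log L_ij + b0 + b1 * group_j + u_j,
  u_j ~ N(0, sigma^2)
```

where `L_ij` is the TMM effective library size (edgeR-style), `u_j` a
patient random intercept, and the reported fold change is `b1 / ln 2`.
The marginal likelihood is maximized with adaptive Gauss–Hermite
quadrature; inference is by Wald or likelihood-ratio test, at alpha 0.025
by default (0.05 split over two co-primary endpoints).

Compartment-level effect sizes are set by **spike-in calibration**: the
endpoint gene's counts in target-class spots are raised by
`r × (per-sample class median)`, a calibration curve maps `r` to the
log2 fold change induced in per-sample pseudobulk, and the curve is
inverted at the bulk-cohort effect size.  A synthetic-data module
generates both the spot reference (compartment blobs on a grid,
log-normal library sizes, NB counts) and a bulk cohort (28 stable / 15
progressor / 15 regressor subjects with fibrosis-stage and NAS
covariates and opposite-direction planted gene-set effects), so the full
workflow runs without external downloads.

## Worked example

```r
library(roipower)

cfg <- sim_config(seed = 11, n_samples = 5, grid_rows = 30, grid_cols = 30,
                  n_genes = 300)
spots <- generate_spot_dataset(cfg)
spots
#> spot_dataset: 300 genes x 4500 spots in 5 samples
#> hepatocyte      niche      other
#>       2965        220       1315

snorm <- normalize_counts(spots$counts, method = "libsize")
seg <- segment_spots(spots,
                     kuppe_score(snorm, cfg$marker_sets$hepatocyte),
                     kuppe_score(snorm, cfg$marker_sets$ecm))
seg
#> segmentation of 4500 spots:
#>      niche hepatocyte      other
#>        364       3251        885
```

The percentile segmentation (ECM score ≥ 85th and hepatocyte score ≤ 15th
percentile for the niche; hepatocyte ≥ 20th and ECM ≤ 80th for the
hepatocyte fraction, per sample) recovers the planted compartments.  Next,
translate a bulk effect of 0.42 log2 into a hepatocyte-compartment spike
fraction and estimate power for 10 patients per group, two 165 µm ROIs
each:

```r
gene <- cfg$marker_sets$lipid[1]
curve <- build_calibration_curve(spots, seg, gene, "hepatocyte",
                                 r_grid = seq(0, 2, by = 0.1))
r_star <- invert_calibration(curve, 0.42)
r_star
#> [1] 0.5026962

spike <- spike_spec(gene, r_star, "hepatocyte")
hep <- seg$labels == "hepatocyte"
pool_control <- restrict_spots(spots, hep)
pool_spiked  <- restrict_spots(apply_spike(spots, spike, seg), hep)

cond <- roi_condition("primary", n_patients_per_group = 10,
                      n_rois_per_patient = 2, roi_diameter_um = 165,
                      spike = spike)
res <- run_condition(cond, pool_control, pool_spiked,
                     run_config(alpha = 0.025, n_reps = 100, seed = 7))
res[c("n_patients", "power", "median_lfc", "lfc_q1", "lfc_q3",
      "convergence_rate")]
#>   n_patients power median_lfc    lfc_q1    lfc_q3 convergence_rate
#> 1         10   0.9  0.4499599 0.3727205 0.5309798                1
```

So a bulk log2 fold change of 0.42 requires spiking roughly half a class
median per spot (`r* ≈ 0.50`; the hepatocyte compartment dominates bulk,
so the spike fraction is close to the bulk effect, whereas the same bulk
effect in the rare niche needs a several-fold larger `r`).  Under that
effect, 10 patients per group with two 165 µm ROIs give an estimated 90%
power at alpha 0.025, with the median recovered fold change (0.45) close
to the planted compartment effect, and every model fit converged.
`run_grid()` sweeps patients × ROIs × diameters, `required_n()` reads off
the smallest adequate design, `dropout_sensitivity()` repeats a condition
with ROIs randomly failing quality control, and `run_pipeline()` chains
all stages (simulate → discover endpoints in bulk → calibrate → power
grid → sensitivity) into a reproducible artifact directory.  A thin CLI
wrapper lives in `inst/cli/roipower.R`.

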