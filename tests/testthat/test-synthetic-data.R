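test_that("spot generation is deterministic given the config", {
  cfg <- small_config()
  a <- generate_spot_dataset(cfg)
  b <- generate_spot_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$spot_meta, b$spot_meta)
  c2 <- generate_spot_dataset(small_config(seed = 43L))
  expect_false(identical(a$counts, c2$counts))
})

test_that("realized compartment fractions track the configured targets", {
  cfg <- sim_config(seed = 5L, n_samples = 5L, grid_rows = 24L,
                    grid_cols = 24L, n_genes = 150L,
                    marker_sets = tiny_marker_sets(150L))
  spots <- generate_spot_dataset(cfg)
  by_sample <- split(spots$spot_meta$true_class, spots$spot_meta$sample_id)
  niche_fr <- vapply(by_sample, function(x) mean(x == "niche"), numeric(1))
  hep_fr <- vapply(by_sample, function(x) mean(x == "hepatocyte"), numeric(1))
  # fibrosis-range niche fractions, per sample
  expect_true(all(niche_fr >= 0.026 & niche_fr <= 0.071))
  expect_true(all(abs(niche_fr - 0.05) / 0.05 <= 0.2))
  expect_true(all(abs(hep_fr - 0.65) / 0.65 <= 0.2))
})

test_that("marker genes are elevated in their home compartment, every sample", {
  spots <- small_spots()
  cfg <- small_config()
  lib <- colSums(spots$counts)
  norm <- sweep(spots$counts, 2, lib / mean(lib), "/")
  hep_score <- colMeans(norm[cfg$marker_sets$hepatocyte, ])
  ecm_score <- colMeans(norm[cfg$marker_sets$ecm, ])
  for (s in unique(spots$spot_meta$sample_id)) {
    hep_i <- spots$spot_meta$sample_id == s &
      spots$spot_meta$true_class == "hepatocyte"
    niche_i <- spots$spot_meta$sample_id == s &
      spots$spot_meta$true_class == "niche"
    expect_gt(mean(hep_score[hep_i]), mean(hep_score[niche_i]))
    expect_gt(mean(ecm_score[niche_i]), mean(ecm_score[hep_i]))
  }
})

test_that("spots are exchangeable across samples (no extra within-sample correlation)", {
  spots <- small_spots()
  set.seed(99)
  # correlations among same-class spots so class structure cannot masquerade
  # as a sample effect
  idx <- which(spots$spot_meta$true_class == "hepatocyte")
  idx <- sample(idx, 60)
  lg <- log1p(spots$counts[, idx])
  rho <- cor(lg, method = "spearman")
  same <- outer(spots$spot_meta$sample_id[idx],
                spots$spot_meta$sample_id[idx], "==")
  diag(same) <- NA
  within <- mean(rho[which(same)], na.rm = TRUE)
  between <- mean(rho[which(!same)], na.rm = TRUE)
  expect_lte(within - between, 0.05)
})

test_that("counts approach the Poisson limit as dispersion grows", {
  cfg <- sim_config(seed = 8L, n_samples = 1L, grid_rows = 40L,
                    grid_cols = 40L, n_genes = 150L,
                    marker_sets = tiny_marker_sets(150L),
                    dispersion = 1e8, libsize_log_sd = 0)
  spots <- generate_spot_dataset(cfg)
  hep <- spots$counts[, spots$spot_meta$true_class == "hepatocyte"]
  m <- rowMeans(hep)
  v <- apply(hep, 1, var)
  ratio <- v[m > 1] / m[m > 1]
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("invalid configurations are rejected", {
  ms <- tiny_marker_sets(150L)
  ms$ecm[1] <- ms$hepatocyte[1]            # overlap
  expect_error(sim_config(n_genes = 150L, marker_sets = ms), "disjoint")
  expect_error(sim_config(niche_fraction = 0.6, hepatocyte_fraction = 0.6),
               "<= 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_genes = 150L,
                          marker_sets = tiny_marker_sets(150L),
                          bulk_n_per_group = c(stable = 0L, progressor = 5L,
                                               regressor = 5L)),
               "subject")
  tiny <- sim_config(seed = 1, n_samples = 1L, grid_rows = 10L,
                     grid_cols = 10L, n_genes = 150L,
                     marker_sets = tiny_marker_sets(150L),
                     niche_fraction = 0.001)
  expect_error(generate_spot_dataset(tiny), "too small")
})

test_that("bulk cohort has the configured group sizes and covariates", {
  cohort <- generate_bulk_cohort(small_config())
  tab <- table(cohort$subject_meta$group)
  expect_equal(unname(tab[c("stable", "progressor", "regressor")]),
               c(28L, 15L, 15L), ignore_attr = TRUE)
  expect_true(all(cohort$subject_meta$NAS >= 0 &
                    cohort$subject_meta$NAS <= 8))
  expect_true(all(cohort$subject_meta$fibrosis_stage %in%
                    paste0("F", 1:4)))
  expect_true(all(cohort$counts >= 0 & cohort$counts == floor(cohort$counts)))
  # deterministic
  expect_identical(cohort$counts, generate_bulk_cohort(small_config())$counts)
})

test_that("null bulk effects give near-zero group differences", {
  cfg <- small_config(seed = 21L,
                      bulk_effect_log2fc = c(lipid = 0, cytoskeleton = 0))
  cohort <- generate_bulk_cohort(cfg)
  norm <- normalize_counts(cohort$counts)
  grp <- cohort$subject_meta$group
  for (set in c("lipid", "cytoskeleton")) {
    v <- colMeans(norm$values[cfg$marker_sets[[set]], ])
    d <- mean(v[grp == "progressor"]) - mean(v[grp == "stable"])
    expect_lt(abs(d), 0.15)
  }
})

test_that("planted bulk log2 effects are recovered on an oversized cohort", {
  cfg <- sim_config(seed = 31L, n_genes = 150L,
                    marker_sets = tiny_marker_sets(150L),
                    bulk_n_per_group = c(stable = 1000L, progressor = 1000L,
                                         regressor = 1000L),
                    bulk_effect_log2fc = c(lipid = 0.42),
                    bulk_libsize_log_mean = log(3e6))
  cohort <- generate_bulk_cohort(cfg)
  grp <- cohort$subject_meta$group
  # depth from the non-planted genes, so the planted set cannot contaminate
  # its own normalization
  unplanted <- setdiff(rownames(cohort$counts), cfg$marker_sets$lipid)
  sf <- normalize_counts(cohort$counts[unplanted, ])$size_factors
  v <- colMeans(log2(sweep(cohort$counts[cfg$marker_sets$lipid, ], 2, sf,
                           "/") + 1))
  d_prog <- mean(v[grp == "progressor"]) - mean(v[grp == "stable"])
  d_regr <- mean(v[grp == "regressor"]) - mean(v[grp == "stable"])
  expect_lt(abs(d_prog - 0.42), 0.02)
  expect_lt(abs(d_regr + 0.42), 0.02)
})
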