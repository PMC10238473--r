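test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 10, 10, 20, 20, 20), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- normalize_counts(m)$size_factors
  # per-gene geometric mean sqrt(200); ratios 10/14.1421 and 20/14.1421
  expect_equal(unname(sf), c(0.70711, 1.41421), tolerance = 1e-4)

  m2 <- cbind(a = c(5, 8, 11), b = c(5, 8, 11))
  expect_equal(unname(normalize_counts(m2)$size_factors), c(1, 1))
})

test_that("size factors are scale-equivariant", {
  set.seed(1)
  m <- matrix(rpois(400, 50) + 1L, nrow = 100)
  # a sample that is exactly c times another gets c times its factor
  m3 <- cbind(m, m[, 2] * 3L)
  sf <- normalize_counts(m3)$size_factors
  expect_lt(abs(sf[5] / sf[2] - 3) / 3, 1e-10)
  # scaling one sample rescales its factor by c relative to the others
  m2 <- m
  m2[, 3] <- m2[, 3] * 3L
  sf1 <- normalize_counts(m)$size_factors
  sf2 <- normalize_counts(m2)$size_factors
  expect_equal((sf2[3] / sf2[1]) / (sf1[3] / sf1[1]), 3, tolerance = 1e-10)
})

test_that("normalization errors are informative", {
  m <- matrix(c(0, 5, 3, 0), nrow = 2)
  expect_error(normalize_counts(m), "libsize")
  expect_error(normalize_counts(matrix(1:4, 2), pseudocount = 0), "> 0")
})

make_screen_data <- function(n_per_group = 40, n_noise = 5, seed = 2,
                             effect = c(prog = -1, regr = 1)) {
  set.seed(seed)
  n <- 3 * n_per_group
  grp <- rep(c("stable", "progressor", "regressor"), each = n_per_group)
  stage <- sample(paste0("F", 1:3), n, replace = TRUE)
  planted <- rnorm(n, 0, 0.2) + effect["prog"] * (grp == "progressor") +
    effect["regr"] * (grp == "regressor")
  same_sign <- rnorm(n, 0, 0.2) + 1 * (grp != "stable")
  noise <- matrix(rnorm(n_noise * n, 0, 1), n_noise)
  Y <- rbind(planted = planted, same_sign = same_sign, noise)
  rownames(Y) <- c("planted", "same_sign", paste0("noise", seq_len(n_noise)))
  list(Y = Y, cov = data.frame(group = grp, fibrosis_stage = stage))
}

test_that("screen selects opposite-direction genes and assigns direction", {
  d <- make_screen_data()
  res <- candidate_gene_screen(as_norm(d$Y), d$cov)
  expect_true(res$selected[res$gene_id == "planted"])
  expect_equal(res$direction[res$gene_id == "planted"], "up_in_regressors")
  expect_false(res$selected[res$gene_id == "same_sign"])
})

test_that("screen null selection rate is far below the nominal cutoffs", {
  set.seed(7)
  n <- 60
  grp <- rep(c("stable", "progressor", "regressor"), each = n / 3)
  stage <- sample(paste0("F", 1:3), n, replace = TRUE)
  Y <- matrix(rnorm(1000 * n), 1000,
              dimnames = list(paste0("g", 1:1000), NULL))
  res <- candidate_gene_screen(as_norm(Y),
                               data.frame(group = grp,
                                          fibrosis_stage = stage))
  expect_lt(mean(res$selected), 0.01)
})

test_that("screen is invariant to gene and sample ordering", {
  d <- make_screen_data(n_per_group = 20)
  res <- candidate_gene_screen(as_norm(d$Y), d$cov)
  gperm <- sample(nrow(d$Y))
  sperm <- sample(ncol(d$Y))
  res_p <- candidate_gene_screen(as_norm(d$Y[gperm, sperm]),
                                 d$cov[sperm, , drop = FALSE])
  res_p <- res_p[match(res$gene_id, res_p$gene_id), ]
  expect_equal(res_p$lfc_prog, res$lfc_prog, tolerance = 1e-10)
  expect_identical(res_p$selected, res$selected)
})

test_that("rank-deficient screen designs yield NA rows, not errors", {
  d <- make_screen_data(n_per_group = 10)
  d$cov$fibrosis_stage <- d$cov$group        # stage aliased with group
  expect_warning(res <- candidate_gene_screen(as_norm(d$Y), d$cov),
                 "rank-deficient")
  expect_true(all(is.na(res$lfc_prog)))
  expect_false(any(res$selected))
})

test_that("summary score runs exactly one filter-and-update pass", {
  v <- c(1, 2, 3, 4)
  Y <- rbind(g1 = v, g2 = v, g3 = 5 - v)
  colnames(Y) <- paste0("s", 1:4)
  sc <- kuppe_score(as_norm(Y), c("g1", "g2", "g3"), name = "toy")
  # g3 is exactly anti-correlated with the initial mean and is dropped;
  # the updated score is the mean of the remaining identical rows
  expect_identical(sc$dropped_genes, "g3")
  expect_equal(unname(sc$values), v)

  ident <- rbind(a = v, b = v, c = v)
  colnames(ident) <- paste0("s", 1:4)
  sc2 <- kuppe_score(as_norm(ident), c("a", "b", "c"))
  expect_length(sc2$dropped_genes, 0)
  expect_equal(unname(sc2$values), v)
})

test_that("a disabled correlation threshold gives the plain mean", {
  set.seed(3)
  Y <- matrix(rnorm(60), 6, dimnames = list(paste0("g", 1:6), NULL))
  sc <- kuppe_score(as_norm(Y), rownames(Y), corr_threshold = -1)
  expect_lt(max(abs(sc$values - colMeans(Y))), 1e-12)
})

test_that("an over-strict threshold that empties the set names it", {
  set.seed(4)
  Y <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(kuppe_score(as_norm(Y), rownames(Y), corr_threshold = 1.01,
                           name = "ecm"), "ecm")
})

test_that("score association recovers planted group shifts and adjusts for confounding", {
  set.seed(5)
  n <- 600
  grp <- sample(c("stable", "progressor", "regressor"), n, replace = TRUE)
  stage_num <- sample(1:4, n, replace = TRUE)
  cov <- data.frame(group = grp, fibrosis_stage = paste0("F", stage_num),
                    NAS = sample(0:8, n, replace = TRUE))
  score <- rnorm(n, 0, 0.5) + 0.42 * (grp == "regressor")
  res <- score_association(score, cov)
  est <- res$estimate[res$contrast == "regressor"]
  expect_lt(abs(est - 0.42), 0.05)
  # null contrast within 3 SE
  p_est <- res$estimate[res$contrast == "progressor"]
  expect_lt(abs(p_est), 3 * res$se[res$contrast == "progressor"])
  # stage-driven score: group effect disappears after adjustment
  score2 <- stage_num + rnorm(n, 0, 0.3)
  res2 <- score_association(score2, cov)
  expect_true(all(res2$p > 0.01))
  expect_error(score_association(rep(1, n), cov), "constant")
})

test_that("co-localization follows rank structure", {
  set.seed(6)
  a <- rnorm(50)
  expect_equal(colocalize_scores(a, exp(a)), 1)
  expect_equal(colocalize_scores(a, -a), -1)
  b <- rnorm(200)
  expect_lt(abs(colocalize_scores(rnorm(200), b)), 0.2)
  expect_warning(r <- colocalize_scores(a[1:2], a[1:2]), "3 observations")
  expect_true(is.na(r))
  per <- colocalize_scores(a, a + rnorm(50, 0, 0.01), by_sample = TRUE,
                           sample_id = rep(c("s1", "s2"), 25))
  expect_named(per, c("s1", "s2"))
  expect_true(all(per > 0.9))
})

test_that("percentile segmentation recovers planted compartments", {
  spots <- ref_spots()
  seg <- ref_segmentation()
  truth <- ref_spots()$spot_meta$true_class
  on_target <- truth %in% c("niche", "hepatocyte")
  agree <- mean((as.character(seg$labels) == truth)[on_target])
  expect_gte(agree, 0.95)
  # partition: every spot gets exactly one label
  expect_equal(length(seg$labels), ncol(spots$counts))
  expect_false(anyNA(seg$labels))
  expect_equal(seg$params[c("ecm_hi_pct", "hep_lo_pct", "hep_hi_pct",
                            "ecm_lo_pct")],
               list(ecm_hi_pct = 85, hep_lo_pct = 15, hep_hi_pct = 20,
                    ecm_lo_pct = 80))
})

test_that("degenerate identical scores give an empty niche", {
  counts <- matrix(5L, 4, 12, dimnames = list(paste0("G%04d", 1:4), NULL))
  rownames(counts) <- sprintf("G%04d", 1:4)
  spots <- toy_spots(counts, rep("S01", 12), rep("other", 12))
  const <- rep(1, 12)
  expect_warning(seg <- segment_spots(spots, const, const), "empty")
  expect_equal(sum(seg$labels == "niche"), 0)
  expect_equal(length(seg$labels), 12L)
})
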