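test_that("TMM factors behave like composition-robust scaling factors", {
  set.seed(20)
  base <- rnbinom(400, mu = 80, size = 5)
  m_same <- cbind(a = base, b = base, c = base)
  els <- tmm_effective_libsize(m_same)
  expect_lt(max(abs(els$tmm_factor - 1)), 1e-12)
  # pure depth change: factors stay ~1, effective sizes scale with depth
  m_depth <- cbind(a = base, b = base, c = 3L * base)
  els2 <- tmm_effective_libsize(m_depth)
  expect_lt(abs(els2$tmm_factor[3] / els2$tmm_factor[1] - 1), 0.01)
  expect_lt(abs(els2$effective[3] / els2$effective[1] - 3) / 3, 0.01)
  # geometric mean of factors is 1
  expect_lt(abs(mean(log(els2$tmm_factor))), 1e-6)
})

test_that("TMM compensates composition bias from a block of up-genes", {
  set.seed(21)
  a <- rnbinom(1000, mu = 50, size = 10)
  b <- a
  up <- 1:100
  b[up] <- b[up] * 8L                        # 10% of genes strongly up in b
  els <- tmm_effective_libsize(cbind(a = a, b = b))
  expect_lt(els$tmm_factor[2] / els$tmm_factor[1], 1)
  expect_error(tmm_effective_libsize(matrix(1, 3, 1)), "2 columns")
})

test_that("NB GLM estimates a null condition effect as zero", {
  y <- rep(c(5L, 9L, 14L, 20L), 2)
  x <- cbind(1, rep(c(0, 1), each = 4))
  fit <- fit_nb_glm(y, x)
  expect_lt(abs(fit$coefficients[2]), 1e-6)
  expect_true(fit$converged)
})

test_that("NB GLM theta grows without bound on Poisson data", {
  set.seed(22)
  big <- replicate(150, {
    y <- rpois(200, 20)
    x <- cbind(1, rep(0:1, each = 100))
    fit_nb_glm(y, x)$theta > 100
  })
  expect_gte(mean(big), 0.9)
})

test_that("NB GLM Wald intervals cover a planted coefficient", {
  set.seed(23)
  hits <- replicate(400, {
    x <- rep(0:1, each = 50)
    mu <- exp(3 + log(2) * x)
    y <- rnbinom(100, mu = mu, size = 4)
    fit <- fit_nb_glm(y, cbind(1, x))
    abs(fit$coefficients[2] - log(2)) < 3 * fit$se[2]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("AGQ marginal likelihood matches the trapezoid oracle", {
  set.seed(24)
  for (i in 1:8) {
    J <- sample(3:6, 1); nr <- sample(2:4, 1)
    sim <- simulate_glmm_counts(J, nr, beta0 = -7.5, lfc = runif(1, -1, 1),
                                sigma_b = runif(1, 0.1, 0.6),
                                theta = runif(1, 2, 10),
                                offset = log(rlnorm(2 * J * nr, log(3e4), 0.3)))
    pars <- list(beta0 = rnorm(1, -7.5, 0.3), beta_group = rnorm(1, 0, 0.3),
                 sigma_b = runif(1, 0.05, 0.5), theta = runif(1, 2, 8))
    agq <- nb_glmm_loglik(pars, sim$y, sim$group, sim$patient, sim$offset)
    ora <- marginal_loglik_oracle(pars, sim$y, sim$group, sim$patient,
                                  sim$offset)
    expect_lt(abs(agq - ora), 1e-3)
  }
})

test_that("the oracle integral is grid-converged and degenerates to the GLM", {
  set.seed(25)
  sim <- simulate_glmm_counts(4, 3, -7, 0.4, 0.3, 5, offset = log(4e4))
  pars <- list(beta0 = -7, beta_group = 0.4 * log(2), sigma_b = 0.3,
               theta = 5)
  l1 <- marginal_loglik_oracle(pars, sim$y, sim$group, sim$patient,
                               sim$offset, grid_points = 2001L)
  l2 <- marginal_loglik_oracle(pars, sim$y, sim$group, sim$patient,
                               sim$offset, grid_points = 4001L)
  expect_lt(abs(l1 - l2), 1e-8)
  # sigma -> 0: the random intercept vanishes and the GLM likelihood remains
  x <- as.numeric(sim$group == "spiked")
  glm_fit <- fit_nb_glm(sim$y, cbind(1, x), offset = sim$offset, theta = 5)
  glm_ll <- sum(dnbinom(sim$y, size = 5,
                        mu = exp(sim$offset - 7 + 0.4 * log(2) * x),
                        log = TRUE))
  tiny <- marginal_loglik_oracle(list(beta0 = -7,
                                      beta_group = 0.4 * log(2),
                                      sigma_b = 1e-6, theta = 5),
                                 sim$y, sim$group, sim$patient, sim$offset)
  expect_lt(abs(tiny - glm_ll), 1e-4)
  agq_tiny <- nb_glmm_loglik(list(beta0 = -7, beta_group = 0.4 * log(2),
                                  sigma_b = 1e-6, theta = 5),
                             sim$y, sim$group, sim$patient, sim$offset)
  expect_lt(abs(agq_tiny - glm_ll), 1e-4)
})

test_that("GLMM fits are insensitive to the quadrature order beyond 15 nodes", {
  set.seed(26)
  sim <- simulate_glmm_counts(8, 2, -7.5, 0.4, 0.3, 5,
                              offset = log(rlnorm(32, log(4e4), 0.2)))
  fit <- fit_nb_glmm(sim$y, sim$group, sim$patient, sim$offset)
  pars <- list(beta0 = fit$beta0, beta_group = fit$beta_group,
               sigma_b = max(fit$sigma_b, 0.05), theta = fit$theta)
  l15 <- nb_glmm_loglik(pars, sim$y, sim$group, sim$patient, sim$offset, 15L)
  l25 <- nb_glmm_loglik(pars, sim$y, sim$group, sim$patient, sim$offset, 25L)
  expect_lt(abs(l15 - l25), 1e-4)
})

test_that("GLMM degenerates cleanly when the random intercept is absent", {
  set.seed(27)
  sim <- simulate_glmm_counts(10, 2, -7.5, 0.5, sigma_b = 0, theta = 6,
                              offset = log(rlnorm(40, log(4e4), 0.2)))
  fit <- fit_nb_glmm(sim$y, sim$group, sim$patient, sim$offset)
  expect_true(fit$converged)
  x <- as.numeric(sim$group == "spiked")
  glm_fit <- fit_nb_glm(sim$y, cbind(1, x), offset = sim$offset)
  if (fit$boundary) {
    expect_lt(abs(fit$loglik - glm_fit$loglik), 1e-6)
    expect_lt(abs(fit$beta_group - glm_fit$coefficients[2]), 1e-3)
  } else {
    # a small positive sigma can fit marginally better; never worse
    expect_gte(fit$loglik, glm_fit$loglik - 1e-6)
    expect_lt(abs(fit$sigma_b), 0.2)
  }
})

test_that("GLMM agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(28)
  sim <- simulate_glmm_counts(15, 3, -7, 0.6, 0.3, 8,
                              offset = log(rlnorm(90, log(4e4), 0.2)))
  ours <- fit_nb_glmm(sim$y, sim$group, sim$patient, sim$offset)
  ext <- suppressWarnings(suppressMessages(
    lme4::glmer.nb(y ~ grp + (1 | pat) + offset(off),
                   data = data.frame(y = sim$y, grp = sim$group,
                                     pat = sim$patient, off = sim$offset))))
  expect_lt(abs(ours$beta_group - lme4::fixef(ext)[2]), 0.05)
  expect_lt(abs(ours$loglik - as.numeric(stats::logLik(ext))), 0.5)
})

test_that("Wald test reports log2 fold change and two-sided p", {
  set.seed(29)
  sim <- simulate_glmm_counts(10, 2, -7.5, 1, 0.2, 5,
                              offset = log(rlnorm(40, log(4e4), 0.2)))
  fit <- fit_nb_glmm(sim$y, sim$group, sim$patient, sim$offset)
  tw <- wald_test(fit)
  expect_equal(tw$lfc, fit$beta_group / log(2))
  expect_equal(tw$p,
               2 * pnorm(-abs(fit$beta_group / fit$se_group)))
  expect_true(tw$p < 0.05)                  # strong planted effect
})

test_that("LRT statistic is non-negative and orders like the Wald test", {
  set.seed(30)
  stats_ok <- TRUE
  pw <- pl <- numeric(0)
  for (i in 1:40) {
    sim <- simulate_glmm_counts(12, 2, -7.5, runif(1, -0.6, 0.6), 0.25, 5,
                                offset = log(rlnorm(48, log(4e4), 0.2)))
    lr <- lrt_test(sim$y, sim$group, sim$patient, sim$offset)
    if (!lr$converged) next
    if (lr$statistic < 0) stats_ok <- FALSE
    wd <- wald_test(lr$fit_full)
    if (wd$converged) {
      pw <- c(pw, wd$p); pl <- c(pl, lr$p)
    }
  }
  expect_true(stats_ok)
  expect_gte(length(pw), 30)
  expect_gte(cor(pw, pl, method = "spearman"), 0.95)
})

test_that("LRT null distribution is approximately chi-square(1)", {
  set.seed(31)
  stats <- replicate(150, {
    sim <- simulate_glmm_counts(8, 2, -7.5, 0, 0.25, 5,
                                offset = log(rlnorm(32, log(4e4), 0.2)))
    lr <- lrt_test(sim$y, sim$group, sim$patient, sim$offset)
    if (lr$converged) lr$statistic else NA_real_
  })
  stats <- stats[!is.na(stats)]
  expect_gte(length(stats), 120)
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})
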