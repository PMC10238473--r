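#' Negative binomial mixed model with a patient random intercept
#'
#' Fits, by maximum marginal likelihood, the model
#' \deqn{y_{ij} ~ NB(\mu_{ij}, \theta), \quad
#'       \log \mu_{ij} = o_{ij} + \beta_0 + \beta_1 group_j + b_j, \quad
#'       b_j ~ N(0, \sigma^2)}
#' where j indexes patients, i ROIs within patient, and the offset o is
#' typically the natural log of the TMM effective library size.  The
#' random-intercept integral is evaluated per patient by adaptive
#' Gauss-Hermite quadrature: nodes are centred at each patient's conditional
#' mode and scaled by the curvature there, so a moderate number of nodes
#' (default 15) suffices.  The four parameters (beta0, beta_group,
#' log theta, log sigma) are optimized by Nelder-Mead, warm-started at the
#' fixed-effect NB GLM solution.
#'
#' When the optimizer drives sigma to the boundary (below exp(-10)) the
#' model degenerates to the fixed-effects NB GLM, which is then refitted
#' directly and reported with \code{sigma_b = 0}.
#'
#' @param y non-negative integer counts, one per ROI.
#' @param group two-level factor (or 0/1 vector) of group membership, or
#'   NULL to fit the null model without a group effect.
#' @param patient factor of patient ids.
#' @param offset log-scale offset per ROI (default 0).
#' @param n_quadrature number of Gauss-Hermite nodes (default 15).
#' @param max_iter Nelder-Mead iteration budget (default 200); one warm
#'   continuation of the same budget is attempted before declaring
#'   non-convergence.
#' @param start optional named start values
#'   \code{c(beta0, beta_group, log_theta, log_sigma)}.
#' @return object of class \code{nb_glmm} with elements \code{beta0},
#'   \code{beta_group}, \code{se_group}, \code{sigma_b}, \code{theta},
#'   \code{loglik}, \code{converged}, \code{n_iter}, \code{n_quadrature},
#'   \code{boundary}, \code{vcov}, \code{null} (TRUE for the no-group
#'   model).  The group effect is on the natural-log scale; divide by
#'   \code{log(2)} for a log2 fold change (see \code{\link{wald_test}}).
#' @examples
#' set.seed(1)
#' sim <- simulate_glmm_counts(n_patients_per_group = 6, n_rois_per_patient = 2,
#'                             beta0 = -8, lfc = 0.5, sigma_b = 0.3, theta = 5,
#'                             offset = log(5e4))
#' fit <- fit_nb_glmm(sim$y, sim$group, sim$patient, sim$offset)
#' coef(fit)
#' @export
fit_nb_glmm <- function(y, group, patient, offset = NULL,
                        n_quadrature = 15L, max_iter = 200L, start = NULL) {
  patient <- factor(patient)
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  null_model <- is.null(group)
  x <- if (null_model) rep(0, n) else group_indicator(group)
  if (!null_model) {
    patients_per_group <- table(tapply(x, patient, max))
    if (length(patients_per_group) < 2L || min(patients_per_group) < 2L)
      stop_fmt("need >= 2 patients per group")
  }
  pid <- as.integer(patient)
  J <- nlevels(patient)

  glm_fit <- fit_nb_glm(y, if (null_model) matrix(1, n) else cbind(1, x),
                        offset = offset)
  if (isTRUE(glm_fit$all_zero))
    return(empty_glmm(null_model, n_quadrature))
  if (is.null(start)) {
    b0 <- glm_fit$coefficients[1L]
    b1 <- if (null_model) NULL else glm_fit$coefficients[2L]
    start <- c(b0, b1, log(max(glm_fit$theta, 1e-3)), log(0.2))
  }

  gh <- gaussHermite(n_quadrature)
  env <- new.env(parent = emptyenv())
  env$bhat <- rep(0, J)
  negll <- make_agq_negloglik(y, x, pid, J, offset, gh, null_model, env)

  k0 <- length(start)
  lower <- c(rep(-Inf, k0 - 2L), -7, -8)
  upper <- c(rep(Inf, k0 - 2L), 12, 3)
  opt <- tryCatch(
    optim(start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = max_iter, factr = 1e7)),
    error = function(e) NULL)
  n_iter <- if (is.null(opt)) 0L else opt$counts[1L]
  if (is.null(opt) || opt$convergence != 0) {
    # fall back to (or polish with) Nelder-Mead from the best point so far
    nm_start <- if (is.null(opt)) start else opt$par
    opt <- optim(nm_start, negll, method = "Nelder-Mead",
                 control = list(maxit = 10L * max_iter, reltol = 1e-10))
    n_iter <- n_iter + opt$counts[1L]
  }
  par <- opt$par
  k <- length(par)
  sigma_b <- exp(par[k])
  # the marginal likelihood is flat in log(sigma) as sigma -> 0; a tiny
  # sigma whose likelihood the fixed-effects GLM matches is a boundary
  # solution, not a convergence failure
  boundary <- sigma_b < exp(-10) ||
    (sigma_b < 1e-3 && is.finite(glm_fit$loglik) &&
       glm_fit$loglik >= -opt$value - 1e-4)
  if (boundary) {
    # random intercept vanished: the marginal model is the NB GLM
    fit <- glm_fit
    out <- list(beta0 = unname(fit$coefficients[1L]),
                beta_group = if (null_model) NA_real_ else
                  unname(fit$coefficients[2L]),
                se_group = if (null_model) NA_real_ else unname(fit$se[2L]),
                sigma_b = 0, theta = fit$theta, loglik = fit$loglik,
                converged = fit$converged, n_iter = n_iter,
                n_quadrature = n_quadrature, boundary = TRUE,
                vcov = NULL, null = null_model)
    class(out) <- "nb_glmm"
    return(out)
  }
  vc <- se_group <- NULL
  if (!null_model) {
    H <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
    vc <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    se_group <- if (!is.null(vc) && vc[2L, 2L] > 0) sqrt(vc[2L, 2L]) else
      NA_real_
  }
  out <- list(beta0 = unname(par[1L]),
              beta_group = if (null_model) NA_real_ else unname(par[2L]),
              se_group = if (null_model) NA_real_ else se_group,
              sigma_b = sigma_b, theta = exp(par[k - 1L]),
              loglik = -opt$value,
              converged = opt$convergence == 0 &&
                (null_model || !is.na(se_group)),
              n_iter = n_iter, n_quadrature = n_quadrature,
              boundary = FALSE, vcov = vc, null = null_model)
  class(out) <- "nb_glmm"
  out
}

group_indicator <- function(group) {
  if (is.numeric(group)) {
    u <- sort(unique(group))
    if (!all(u %in% c(0, 1))) stop_fmt("numeric group must be 0/1")
    return(as.numeric(group))
  }
  g <- factor(group)
  if (nlevels(g) != 2L) stop_fmt("group must have exactly 2 levels")
  as.numeric(g == levels(g)[2L])
}

empty_glmm <- function(null_model, n_quadrature) {
  structure(list(beta0 = NA_real_, beta_group = NA_real_, se_group = NA_real_,
                 sigma_b = NA_real_, theta = NA_real_, loglik = NA_real_,
                 converged = FALSE, n_iter = 0L, n_quadrature = n_quadrature,
                 boundary = FALSE, vcov = NULL, null = null_model),
            class = "nb_glmm")
}

# negative AGQ marginal log-likelihood closure; per-patient conditional
# modes are warm-started across evaluations through `env`
make_agq_negloglik <- function(y, x, pid, J, offset, gh, null_model, env) {
  force(env)
  lw0 <- log(gh$w) + gh$x^2
  sq2 <- sqrt(2)
  function(par) {
    k <- length(par)
    b0 <- par[1L]
    b1 <- if (null_model) 0 else par[2L]
    theta <- exp(par[k - 1L]); sigma <- exp(par[k])
    if (!is.finite(theta) || !is.finite(sigma)) return(1e10)
    eta0 <- offset + b0 + b1 * x
    bhat <- env$bhat
    h2 <- NULL
    for (it in 1:50) {
      mu <- exp(eta0 + bhat[pid])
      g1 <- rowsum(y - (y + theta) * mu / (mu + theta), pid)[, 1L] -
        bhat / sigma^2
      h2 <- -rowsum((y + theta) * theta * mu / (mu + theta)^2, pid)[, 1L] -
        1 / sigma^2
      step <- g1 / h2
      bhat <- bhat - step
      if (max(abs(step)) < 1e-10) break
    }
    env$bhat <- bhat
    tau <- 1 / sqrt(-h2)
    lw <- matrix(0, J, length(gh$x))
    for (q in seq_along(gh$x)) {
      bq <- bhat + sq2 * tau * gh$x[q]
      mu <- exp(eta0 + bq[pid])
      hq <- rowsum(dnbinom(y, size = theta, mu = mu, log = TRUE), pid)[, 1L] +
        dnorm(bq, 0, sigma, log = TRUE)
      lw[, q] <- lw0[q] + hq
    }
    ll <- sum(row_logsumexp(lw)) + sum(log(sq2 * tau))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Evaluate the AGQ marginal log-likelihood at given parameters
#'
#' @param params named vector or list with \code{beta0}, \code{beta_group},
#'   \code{sigma_b}, \code{theta}.
#' @param y,group,patient,offset data as in \code{\link{fit_nb_glmm}}.
#' @param n_quadrature Gauss-Hermite nodes (default 15).
#' @return the marginal log-likelihood.
#' @export
nb_glmm_loglik <- function(params, y, group, patient, offset = NULL,
                           n_quadrature = 15L) {
  params <- as.list(params)
  patient <- factor(patient)
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  x <- if (is.null(group)) rep(0, n) else group_indicator(group)
  env <- new.env(parent = emptyenv())
  env$bhat <- rep(0, nlevels(patient))
  negll <- make_agq_negloglik(y, x, as.integer(patient), nlevels(patient),
                              offset, gaussHermite(n_quadrature),
                              is.null(group), env)
  par <- c(params$beta0, if (!is.null(group)) params$beta_group,
           log(params$theta), log(params$sigma_b))
  -negll(par)
}

#' Brute-force marginal log-likelihood by dense trapezoid integration
#'
#' Validation oracle for the adaptive quadrature: each patient's
#' random-intercept integral is evaluated by the trapezoid rule on a dense
#' grid spanning \code{grid_halfwidth} standard deviations either side of
#' zero.  Independent of the quadrature code path.
#'
#' @param params named vector/list with \code{beta0}, \code{beta_group},
#'   \code{sigma_b} (> 0), \code{theta}.
#' @param y,group,patient,offset data as in \code{\link{fit_nb_glmm}}.
#' @param grid_halfwidth half-width of the integration grid in units of
#'   sigma_b (default 8).
#' @param grid_points number of grid points (default 2001).
#' @return the marginal log-likelihood.
#' @export
marginal_loglik_oracle <- function(params, y, group, patient, offset = NULL,
                                   grid_halfwidth = 8, grid_points = 2001L) {
  params <- as.list(params)
  sigma <- params$sigma_b; theta <- params$theta
  if (sigma <= 0) stop_fmt("oracle requires sigma_b > 0")
  patient <- factor(patient)
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  x <- if (is.null(group)) rep(0, n) else group_indicator(group)
  b1 <- if (is.null(group)) 0 else params$beta_group
  eta0 <- offset + params$beta0 + b1 * x
  bg <- seq(-grid_halfwidth * sigma, grid_halfwidth * sigma,
            length.out = grid_points)
  db <- bg[2L] - bg[1L]
  w <- rep(1, grid_points); w[c(1L, grid_points)] <- 0.5
  total <- 0
  for (j in levels(patient)) {
    i <- patient == j
    hj <- vapply(bg, function(b)
      sum(dnbinom(y[i], size = theta, mu = exp(eta0[i] + b), log = TRUE)),
      numeric(1)) + dnorm(bg, 0, sigma, log = TRUE)
    m <- max(hj)
    total <- total + m + log(sum(w * exp(hj - m)) * db)
  }
  total
}

#' Simulate counts from the NB random-intercept model
#'
#' Draws a balanced two-group dataset directly from the generative model of
#' \code{\link{fit_nb_glmm}} -- used for parameter-recovery and calibration
#' studies.
#'
#' @param n_patients_per_group,n_rois_per_patient design sizes.
#' @param beta0 intercept on the natural-log scale.
#' @param lfc group effect in log2 units (beta_group = lfc * log 2).
#' @param sigma_b random-intercept SD.
#' @param theta NB size parameter.
#' @param offset scalar or per-ROI log offset (e.g. log effective library
#'   size); scalar values are recycled.
#' @return list with \code{y}, \code{group} (factor control/spiked),
#'   \code{patient} (factor) and \code{offset}.
#' @export
simulate_glmm_counts <- function(n_patients_per_group, n_rois_per_patient,
                                 beta0, lfc, sigma_b, theta, offset = 0) {
  J <- 2L * n_patients_per_group
  n <- J * n_rois_per_patient
  patient <- factor(rep(sprintf("P%02d", seq_len(J)),
                        each = n_rois_per_patient))
  group <- factor(rep(c("control", "spiked"),
                      each = n_patients_per_group * n_rois_per_patient),
                  levels = c("control", "spiked"))
  offset <- rep(offset, length.out = n)
  b <- rnorm(J, 0, sigma_b)
  eta <- offset + beta0 + lfc * log(2) * (group == "spiked") +
    b[as.integer(patient)]
  list(y = rnbinom(n, size = theta, mu = exp(eta)), group = group,
       patient = patient, offset = offset)
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat("NB GLMM (AGQ,", x$n_quadrature, "nodes)",
      if (x$null) "[null model]" else "", "\n")
  cat(sprintf("  beta0 = %.4f  beta_group = %.4f (lfc = %.3f log2)\n",
              x$beta0, x$beta_group, x$beta_group / log(2)))
  cat(sprintf("  sigma_b = %.4f  theta = %.3f  logLik = %.4f\n",
              x$sigma_b, x$theta, x$loglik))
  cat("  converged:", x$converged,
      if (x$boundary) "(sigma at boundary, refitted as GLM)" else "", "\n")
  invisible(x)
}

#' @export
summary.nb_glmm <- function(object, ...) {
  z <- object$beta_group / object$se_group
  out <- list(fit = object,
              table = data.frame(estimate = object$beta_group,
                                 se = object$se_group, z = z,
                                 p = 2 * pnorm(-abs(z)),
                                 lfc_log2 = object$beta_group / log(2),
                                 row.names = "group"))
  class(out) <- "summary.nb_glmm"
  out
}

#' @export
print.summary.nb_glmm <- function(x, ...) {
  print(x$fit)
  if (!x$fit$null) print(x$table)
  invisible(x)
}

#' @export
coef.nb_glmm <- function(object, ...) {
  c(beta0 = object$beta0, beta_group = object$beta_group,
    sigma_b = object$sigma_b, theta = object$theta)
}

#' @export
logLik.nb_glmm <- function(object, ...) {
  structure(object$loglik, df = if (object$null) 3L else 4L,
            class = "logLik")
}

#' @export
vcov.nb_glmm <- function(object, ...) object$vcov
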