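#' Negative binomial GLM with profiled dispersion
#'
#' Maximum-likelihood negative binomial regression with log link and an
#' optional offset.  For fixed theta the coefficients are fitted by
#' iteratively reweighted least squares (\code{glm.fit} with the
#' \code{MASS::negative.binomial} family); theta is profiled by maximizing
#' the NB log-likelihood over log(theta) on [-7, 12].  Wald standard errors
#' come from the expected information at the optimum.
#'
#' @param y non-negative integer response vector.
#' @param design design matrix (including intercept) or data.frame coerced
#'   via \code{model.matrix(~ .)}.
#' @param offset log-scale offset per observation (default 0), e.g. the log
#'   effective library size.
#' @param theta optional fixed dispersion; when NULL (default) theta is
#'   estimated by profile ML.
#' @return object of class \code{nb_glm}: list with \code{coefficients},
#'   \code{se}, \code{theta}, \code{loglik}, \code{fitted}, \code{converged},
#'   \code{df_residual}.
#' @seealso \code{\link{fit_nb_glmm}} for the random-intercept extension.
#' @export
fit_nb_glm <- function(y, design, offset = NULL, theta = NULL) {
  if (is.data.frame(design))
    design <- stats::model.matrix(~ ., data = design)
  X <- as.matrix(design)
  if (is.null(offset)) offset <- rep(0, length(y))
  if (any(y < 0) || any(y != floor(y)))
    stop_fmt("fit_nb_glm: y must be non-negative integers")
  if (all(y == 0))
    return(structure(list(coefficients = setNames(rep(NA_real_, ncol(X)),
                                                  colnames(X)),
                          se = rep(NA_real_, ncol(X)), theta = NA_real_,
                          loglik = NA_real_, fitted = rep(0, length(y)),
                          converged = FALSE, all_zero = TRUE,
                          df_residual = length(y) - ncol(X)),
                     class = "nb_glm"))
  if (qr(X)$rank < ncol(X))
    stop_fmt("fit_nb_glm: design matrix is rank deficient")

  fit_at <- function(th) {
    suppressWarnings(glm.fit(X, y, offset = offset,
                             family = MASS::negative.binomial(th),
                             control = list(epsilon = 1e-12, maxit = 100)))
  }
  ll_at <- function(th) {
    f <- fit_at(th)
    sum(dnbinom(y, size = th, mu = f$fitted.values, log = TRUE))
  }
  if (is.null(theta)) {
    opt <- optimize(function(lt) ll_at(exp(lt)), c(-7, 12), maximum = TRUE,
                    tol = 1e-8)
    theta <- exp(opt$maximum)
  }
  f <- fit_at(theta)
  mu <- f$fitted.values
  w <- mu / (1 + mu / theta)               # expected information weights
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(chol2inv(chol(info)))),
                 error = function(e) rep(NA_real_, ncol(X)))
  structure(list(coefficients = setNames(f$coefficients, colnames(X)),
                 se = setNames(se, colnames(X)), theta = theta,
                 loglik = sum(dnbinom(y, size = theta, mu = mu, log = TRUE)),
                 fitted = mu, converged = isTRUE(f$converged),
                 all_zero = FALSE, df_residual = length(y) - ncol(X)),
            class = "nb_glm")
}

#' @export
print.nb_glm <- function(x, ...) {
  cat("Negative binomial GLM (theta =", format(x$theta, digits = 4),
      ", logLik =", format(x$loglik, digits = 8), ")\n")
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' @export
coef.nb_glm <- function(object, ...) object$coefficients

#' @export
logLik.nb_glm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}
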