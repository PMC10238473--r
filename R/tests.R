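#' Wald test of the group effect in a fitted NB GLMM
#'
#' Two-sided test of beta_group = 0 from the coefficient/standard-error
#' ratio against the standard normal.
#'
#' @param fit a converged \code{\link{fit_nb_glmm}} object (with a group
#'   effect).
#' @return object of class \code{roi_test}: list with \code{method}
#'   ("wald_glmm"), \code{lfc} (log2), \code{se_lfc}, \code{p},
#'   \code{converged}.  Non-converged fits give p = NA.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "nb_glmm"))
  if (fit$null) stop_fmt("wald_test needs a model with a group effect")
  if (!fit$converged || is.na(fit$se_group))
    return(structure(list(method = "wald_glmm",
                          lfc = fit$beta_group / log(2), se_lfc = NA_real_,
                          p = NA_real_, converged = FALSE),
                     class = "roi_test"))
  z <- fit$beta_group / fit$se_group
  structure(list(method = "wald_glmm", lfc = fit$beta_group / log(2),
                 se_lfc = fit$se_group / log(2), p = 2 * pnorm(-abs(z)),
                 converged = TRUE), class = "roi_test")
}

#' Likelihood-ratio test of the group effect
#'
#' Fits the full NB GLMM (offset + group + patient random intercept) and the
#' nested null model without the group term on the same data, and refers
#' twice the log-likelihood difference to chi-square with 1 df.  The full
#' model is additionally warm-started from the null solution so that the
#' statistic is non-negative whenever both fits converge; the test is
#' flagged non-converged if either fit fails.
#'
#' @param y,group,patient,offset data as in \code{\link{fit_nb_glmm}}.
#' @param n_quadrature,max_iter passed to both fits.
#' @return object of class \code{roi_test} with \code{method} "lrt_glmm",
#'   \code{lfc} (log2, from the full fit), \code{statistic}, \code{p},
#'   \code{converged}, plus the two fits as \code{fit_full}, \code{fit_null}.
#' @export
lrt_test <- function(y, group, patient, offset = NULL, n_quadrature = 15L,
                     max_iter = 200L) {
  full <- fit_nb_glmm(y, group, patient, offset, n_quadrature, max_iter)
  null <- fit_nb_glmm(y, NULL, patient, offset, n_quadrature, max_iter)
  # nesting guard: restart the full model from the null optimum if needed
  if (is.finite(full$loglik) && is.finite(null$loglik) &&
      full$loglik < null$loglik) {
    restart <- c(null$beta0, 0, log(max(null$theta, 1e-3)),
                 log(max(null$sigma_b, 1e-3)))
    refit <- fit_nb_glmm(y, group, patient, offset, n_quadrature, max_iter,
                         start = restart)
    if (is.finite(refit$loglik) && refit$loglik > full$loglik) full <- refit
  }
  ok <- full$converged && null$converged &&
    is.finite(full$loglik) && is.finite(null$loglik)
  stat <- if (ok) max(0, 2 * (full$loglik - null$loglik)) else NA_real_
  structure(list(method = "lrt_glmm", lfc = full$beta_group / log(2),
                 statistic = stat,
                 p = if (ok) pchisq(stat, df = 1, lower.tail = FALSE)
                     else NA_real_,
                 converged = ok, fit_full = full, fit_null = null),
            class = "roi_test")
}

#' @export
print.roi_test <- function(x, ...) {
  cat(sprintf("%s: lfc = %.3f (log2), p = %s, converged = %s\n", x$method,
              x$lfc, format.pval(x$p, digits = 3), x$converged))
  invisible(x)
}
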