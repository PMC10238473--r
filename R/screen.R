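#' Candidate-gene screen for opposite-direction outcome effects
#'
#' Per-gene ordinary least squares of normalized expression on outcome group
#' (two dummy contrasts, progressor and regressor vs stable) adjusted for
#' baseline fibrosis stage (categorical).  A gene is selected as a candidate
#' endpoint when its progressor and regressor log2 fold changes have opposite
#' signs and both raw p-values are below \code{p_cutoff} -- the screen is a
#' hypothesis-generation step, so no multiplicity correction is applied.
#'
#' @param norm a \code{\link{normalize_counts}} result (log2 values).
#' @param covariates data.frame with columns \code{group} (levels stable,
#'   progressor, regressor) and \code{fibrosis_stage}, one row per sample of
#'   \code{norm}, in column order.
#' @param p_cutoff raw p-value threshold applied to both contrasts
#'   (default 0.05).
#' @return data.frame of class \code{screen_result}, one row per gene:
#'   \code{lfc_prog}, \code{lfc_regr} (log2), \code{p_prog}, \code{p_regr},
#'   \code{selected}, \code{direction} ("up_in_progressors" or
#'   "up_in_regressors" for selected genes, NA otherwise).
#' @export
candidate_gene_screen <- function(norm, covariates, p_cutoff = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  Y <- norm$values
  if (nrow(covariates) != ncol(Y))
    stop_fmt("covariates rows (%d) must match samples (%d)",
             nrow(covariates), ncol(Y))
  grp <- factor(covariates$group,
                levels = c("stable", "progressor", "regressor"))
  if (any(table(grp) < 2))
    stop_fmt("candidate_gene_screen needs >= 2 subjects per group")
  X <- stats::model.matrix(~ grp + factor(covariates$fibrosis_stage))
  res <- screen_ols(Y, X, prog_col = 2L, regr_col = 3L)
  res$selected <- !is.na(res$p_prog) &
    sign(res$lfc_prog) != sign(res$lfc_regr) &
    res$p_prog < p_cutoff & res$p_regr < p_cutoff
  res$direction <- ifelse(res$selected,
                          ifelse(res$lfc_regr > 0, "up_in_regressors",
                                 "up_in_progressors"), NA_character_)
  class(res) <- c("screen_result", "data.frame")
  res
}

# vectorized OLS over all genes with shared design; returns NA rows (with a
# warning) instead of failing when the design is rank deficient
screen_ols <- function(Y, X, prog_col, regr_col) {
  g <- rownames(Y)
  if (is.null(g)) g <- paste0("gene", seq_len(nrow(Y)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warn_fmt("rank-deficient design (rank %d < %d); returning NA results",
             qx$rank, ncol(X))
    return(data.frame(gene_id = g, lfc_prog = NA_real_, lfc_regr = NA_real_,
                      p_prog = NA_real_, p_regr = NA_real_,
                      stringsAsFactors = FALSE))
  }
  n <- ncol(Y); p <- ncol(X)
  B <- t(qr.coef(qx, t(Y)))                       # genes x p
  resid <- t(Y) - X %*% t(B)
  s2 <- colSums(resid^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))
  se_prog <- sqrt(s2 * xtx_inv[prog_col, prog_col])
  se_regr <- sqrt(s2 * xtx_inv[regr_col, regr_col])
  t_prog <- B[, prog_col] / se_prog
  t_regr <- B[, regr_col] / se_regr
  df <- n - p
  data.frame(gene_id = g,
             lfc_prog = B[, prog_col], lfc_regr = B[, regr_col],
             p_prog = 2 * pt(-abs(t_prog), df),
             p_regr = 2 * pt(-abs(t_regr), df),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association of a summary score with outcome group
#'
#' OLS of a gene-set summary score on outcome group adjusted for baseline
#' fibrosis stage and NAS, reporting the group contrasts vs stable.
#'
#' @param score a \code{\link{kuppe_score}} result (or any numeric vector of
#'   per-subject scores).
#' @param covariates data.frame with \code{group}, \code{fibrosis_stage} and
#'   \code{NAS}.
#' @return data.frame with one row per group contrast: estimate, se,
#'   t value, p value.
#' @export
score_association <- function(score, covariates) {
  y <- if (inherits(score, "summary_score")) score$values else score
  if (length(y) != nrow(covariates))
    stop_fmt("score length (%d) must match covariate rows (%d)",
             length(y), nrow(covariates))
  if (sd(y) == 0) stop_fmt("score is constant; association model undefined")
  grp <- factor(covariates$group,
                levels = c("stable", "progressor", "regressor"))
  fit <- lm(y ~ grp + factor(covariates$fibrosis_stage) + covariates$NAS)
  cf <- summary(fit)$coefficients
  rows <- grep("^grp", rownames(cf))
  out <- data.frame(contrast = sub("^grp", "", rownames(cf)[rows]),
                    estimate = cf[rows, 1], se = cf[rows, 2],
                    t = cf[rows, 3], p = cf[rows, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
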