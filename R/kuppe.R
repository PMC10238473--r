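#' Gene-set summary score with correlation filtering
#'
#' Two-pass summary score: (1) average the normalized expression of all genes
#' in the set; (2) drop members whose correlation with that initial average is
#' below \code{corr_threshold} (default 0.1) and recompute the average over
#' the retained genes.  The filter runs exactly one cycle -- it is not
#' iterated to convergence.  Setting \code{corr_threshold = -1} disables the
#' filter, making the score the plain arithmetic mean.
#'
#' Genes whose correlation is undefined (zero variance in the gene or in the
#' initial average) are retained, so a set of identical rows scores as that
#' row with no gene dropped.
#'
#' @param norm a \code{\link{normalize_counts}} result, or a bare numeric
#'   matrix of log-scale values (genes x samples or genes x spots).
#' @param gene_set character vector of gene ids, all present in the matrix.
#' @param corr_threshold correlation cutoff (default 0.1).
#' @param method correlation flavour, "pearson" (default) or "spearman".
#' @param name optional label stored with the score.
#' @return object of class \code{summary_score}: list with \code{values}
#'   (named per column), \code{retained_genes}, \code{dropped_genes},
#'   \code{correlations}, \code{corr_threshold}, \code{gene_set_name}.
#' @export
kuppe_score <- function(norm, gene_set, corr_threshold = 0.1,
                        method = c("pearson", "spearman"), name = NULL) {
  method <- match.arg(method)
  V <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  if (!length(gene_set)) stop_fmt("gene set%s is empty",
                                  if (is.null(name)) "" else paste0(" '", name, "'"))
  missing <- setdiff(gene_set, rownames(V))
  if (length(missing))
    stop_fmt("gene set%s: %d gene(s) not in matrix (e.g. %s)",
             if (is.null(name)) "" else paste0(" '", name, "'"),
             length(missing), missing[1L])
  sub <- V[gene_set, , drop = FALSE]
  m0 <- colMeans(sub)
  cc <- apply(sub, 1L, function(v) {
    if (sd(v) == 0 || sd(m0) == 0) return(NA_real_)
    cor(v, m0, method = method)
  })
  keep <- is.na(cc) | cc >= corr_threshold
  if (!any(keep))
    stop_fmt("all genes of set%s fall below the correlation threshold %g",
             if (is.null(name)) "" else paste0(" '", name, "'"),
             corr_threshold)
  out <- list(values = colMeans(sub[keep, , drop = FALSE]),
              retained_genes = gene_set[keep],
              dropped_genes = gene_set[!keep],
              correlations = cc, corr_threshold = corr_threshold,
              method = method,
              gene_set_name = if (is.null(name)) "gene_set" else name)
  class(out) <- "summary_score"
  out
}

#' @export
print.summary_score <- function(x, ...) {
  cat("summary_score '", x$gene_set_name, "': ", length(x$retained_genes),
      " genes retained (", length(x$dropped_genes), " dropped at r < ",
      x$corr_threshold, ") over ", length(x$values), " columns\n", sep = "")
  invisible(x)
}

#' Co-localization of two summary scores
#'
#' Spearman rank correlation between two scores over shared samples or spots.
#' Two expression signals are said to co-localize when their summary scores
#' correlate both in bulk and, per sample, across the tissue area in spatial
#' data; \code{by_sample = TRUE} computes the correlation within each sample
#' separately.
#'
#' @param score_a,score_b \code{summary_score} objects or numeric vectors on
#'   aligned columns.
#' @param by_sample compute per-sample correlations.
#' @param sample_id per-column sample labels, required when
#'   \code{by_sample = TRUE}.
#' @return a single Spearman rho, or a named vector per sample.  Samples with
#'   fewer than 3 observations give NA with a warning.
#' @export
colocalize_scores <- function(score_a, score_b, by_sample = FALSE,
                              sample_id = NULL) {
  a <- if (inherits(score_a, "summary_score")) score_a$values else score_a
  b <- if (inherits(score_b, "summary_score")) score_b$values else score_b
  if (length(a) != length(b))
    stop_fmt("scores have different lengths (%d vs %d)", length(a), length(b))
  rho1 <- function(x, y) {
    if (length(x) < 3) {
      warn_fmt("fewer than 3 observations; returning NA")
      return(NA_real_)
    }
    cor(x, y, method = "spearman")
  }
  if (!by_sample) return(rho1(a, b))
  if (is.null(sample_id))
    stop_fmt("by_sample = TRUE requires sample_id")
  vapply(split(seq_along(a), sample_id),
         function(i) rho1(a[i], b[i]), numeric(1))
}
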