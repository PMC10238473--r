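#' TMM effective library sizes
#'
#' Trimmed-mean-of-M-values normalization factors (computed with
#' \code{edgeR::calcNormFactors}) times raw library sizes.  The reference
#' column is the one whose upper-quartile/library-size ratio is closest to
#' the mean such ratio; per-column factors are variance-weighted trimmed
#' means of gene-wise log2 ratios against the reference, rescaled so their
#' geometric mean is 1.  The natural log of the effective library size is
#' the offset of the downstream count models.
#'
#' @param counts count matrix genes x ROIs (composite rows should be
#'   excluded by the caller).
#' @param trim_m trim fraction on log-ratios (default 0.3).
#' @param trim_a trim fraction on average log intensity (default 0.05).
#' @return object of class \code{eff_libsize}: list with
#'   \code{raw_libsize}, \code{tmm_factor}, \code{effective} and
#'   \code{reference_index}.
#' @export
tmm_effective_libsize <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_fmt("TMM needs at least 2 columns")
  lib <- colSums(counts)
  if (any(lib == 0)) stop_fmt("column %d has zero library size",
                              which(lib == 0)[1L])
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  # reference column as chosen by the TMM method: upper quartile fraction
  # closest to the mean
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  out <- list(raw_libsize = lib, tmm_factor = f, effective = lib * f,
              reference_index = unname(ref))
  class(out) <- "eff_libsize"
  out
}

#' @export
print.eff_libsize <- function(x, ...) {
  cat("TMM effective library sizes for", length(x$effective), "columns",
      "(reference column", x$reference_index, ")\n")
  print(summary(x$effective))
  invisible(x)
}
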