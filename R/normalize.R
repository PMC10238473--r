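#' Depth-normalize a count matrix to log2 scale
#'
#' Size-factor normalization followed by \code{log2(count / sf + pseudocount)}.
#' The default size factors use the median-of-ratios method: each sample's
#' factor is the median, over genes expressed in every sample, of the ratio of
#' its count to the per-gene geometric mean.  This is a depth-corrected
#' log-scale transform with the same semantics as regularized-log pipelines
#' for bulk data (scale-equivariant: doubling a sample's counts doubles its
#' size factor and leaves its normalized values unchanged).
#'
#' For sparse spot-level matrices no gene may be expressed in every column and
#' the median-of-ratios factor is undefined; \code{method = "libsize"} then
#' uses total counts referenced to their geometric mean.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @param pseudocount positive pseudocount added before the log (default 1).
#' @param method "median_ratios" (default) or "libsize".
#' @return object of class \code{normalized_matrix}: list with \code{values}
#'   (log2 scale, genes x samples), \code{size_factors} and \code{pseudocount}.
#' @examples
#' m <- matrix(c(10, 10, 10, 20, 20, 20), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' normalize_counts(m)$size_factors
#' @export
normalize_counts <- function(counts, pseudocount = 1,
                             method = c("median_ratios", "libsize")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (pseudocount <= 0) stop_fmt("pseudocount must be > 0")
  if (method == "median_ratios") {
    expressed <- rowSums(counts > 0) == ncol(counts)
    if (!any(expressed))
      stop_fmt(paste0("no gene has nonzero counts in every sample; filter ",
                      "low-coverage genes or use method = \"libsize\""))
    lg <- log(counts[expressed, , drop = FALSE])
    geo <- exp(rowMeans(lg))
    sf <- apply(counts[expressed, , drop = FALSE] / geo, 2, median)
  } else {
    lib <- colSums(counts)
    if (any(lib == 0)) stop_fmt("normalize_counts: sample with zero counts")
    sf <- lib / geometric_mean(lib)
  }
  values <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  out <- list(values = values, size_factors = sf, pseudocount = pseudocount,
              method = method)
  class(out) <- "normalized_matrix"
  out
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (log2):", nrow(x$values), "genes x", ncol(x$values),
      "samples;", x$method, "size factors\n")
  invisible(x)
}
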