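#' Paired negative binomial log2 fold change between two pseudobulk matrices
#'
#' Tests one gene for a condition effect between two count matrices sharing
#' the same samples (e.g. spiked-in vs unmodified pseudobulk).  The model is
#' a negative binomial log-linear regression of the gene's counts on
#' condition plus sample as a fixed-effect covariate, with a log
#' size-factor offset (median-of-ratios factors computed across all 2n
#' columns jointly); gene-wise dispersion is estimated by profile maximum
#' likelihood under that design.  The reported fold change is the condition
#' coefficient divided by ln 2.
#'
#' @param bulk_a,bulk_b count matrices genes x samples with identical sample
#'   sets; \code{bulk_b} is the "treated" condition (positive lfc means
#'   higher in \code{bulk_b}).
#' @param gene gene id to test.
#' @return list with \code{lfc} (log2), \code{se}, \code{p} (Wald),
#'   \code{theta}, \code{converged}, \code{all_zero}.
#' @export
paired_nb_log2fc <- function(bulk_a, bulk_b, gene) {
  if (!identical(dim(bulk_a), dim(bulk_b)))
    stop_fmt("paired matrices must have identical dimensions")
  if (!gene %in% rownames(bulk_a))
    stop_fmt("gene %s not present", gene)
  n <- ncol(bulk_a)
  combined <- cbind(bulk_a, bulk_b)
  sf <- tryCatch(normalize_counts(combined)$size_factors,
                 error = function(e) normalize_counts(combined,
                                                      method = "libsize")$size_factors)
  y <- as.numeric(combined[gene, ])
  if (all(y == 0))
    return(list(lfc = NA_real_, se = NA_real_, p = NA_real_,
                theta = NA_real_, converged = FALSE, all_zero = TRUE))
  cond <- rep(c(0, 1), each = n)
  samp <- factor(rep(seq_len(n), 2))
  X <- stats::model.matrix(~ cond + samp)
  fit <- fit_nb_glm(y, X, offset = log(sf))
  b <- fit$coefficients["cond"]; se <- fit$se["cond"]
  list(lfc = unname(b) / log(2), se = unname(se) / log(2),
       p = unname(2 * pnorm(-abs(b / se))), theta = fit$theta,
       converged = fit$converged, all_zero = FALSE)
}

#' Build a spike-in calibration curve
#'
#' Maps the spike-in fraction r to the log2 fold change it induces in
#' pseudobulk tissue: for each r on the grid the target gene is spiked into
#' the target compartment, all spots are summed into per-sample pseudobulk,
#' and the paired NB fold change against the unmodified pseudobulk is
#' recorded.  Inverting the curve (\code{\link{invert_calibration}}) picks
#' the r whose bulk-tissue fold change matches an observed bulk effect size.
#'
#' @param spots a \code{spot_dataset}.
#' @param labels a \code{segmentation} (or per-spot label vector).
#' @param gene gene id to spike.
#' @param target_class "niche" or "hepatocyte".
#' @param r_grid increasing non-negative grid including 0
#'   (default \code{seq(0, 4, by = 0.1)}).
#' @param integer_counts round spike increments (default TRUE).
#' @return object of class \code{calibration_curve}: data.frame columns
#'   \code{r}, \code{lfc}, \code{se}, \code{p}, with attributes \code{gene}
#'   and \code{target_class}.
#' @export
build_calibration_curve <- function(spots, labels, gene,
                                    target_class = c("niche", "hepatocyte"),
                                    r_grid = seq(0, 4, by = 0.1),
                                    integer_counts = TRUE) {
  target_class <- match.arg(target_class)
  if (!0 %in% r_grid) stop_fmt("r_grid must include 0")
  if (is.unsorted(r_grid, strictly = TRUE))
    stop_fmt("r_grid must be strictly increasing")
  pb0 <- pseudobulk(spots)
  lab <- if (inherits(labels, "segmentation")) labels$labels else labels
  # the spike only changes one gene's row; update the pseudobulk directly
  samples <- colnames(pb0)
  class_idx <- lapply(samples, function(s)
    which(spots$spot_meta$sample_id == s & as.character(lab) == target_class))
  med <- vapply(class_idx, function(i)
    if (length(i)) median(spots$counts[gene, i]) else NA_real_, numeric(1))
  nspots <- vapply(class_idx, length, integer(1))
  rows <- lapply(r_grid, function(r) {
    pb_r <- pb0
    inc <- r * med
    if (integer_counts) inc <- round_half_up(inc)
    add <- ifelse(nspots > 0, inc * nspots, 0)
    pb_r[gene, ] <- pb_r[gene, ] + add
    res <- paired_nb_log2fc(pb0, pb_r, gene)
    data.frame(r = r, lfc = res$lfc, se = res$se, p = res$p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_curve", "data.frame")
  attr(out, "gene") <- gene
  attr(out, "target_class") <- target_class
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$r, x$lfc, type = "b", pch = 16,
                 xlab = "spike-in fraction r",
                 ylab = "pseudobulk log2 fold change",
                 main = sprintf("Calibration: %s in %s", attr(x, "gene"),
                                attr(x, "target_class")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Invert a calibration curve at a target log2 fold change
#'
#' Finds the spike-in fraction whose pseudobulk fold change matches an
#' observed bulk effect size, by linear interpolation between the bracketing
#' grid points.  If the curve is non-monotone the smallest bracketing
#' solution is returned.
#'
#' @param curve a \code{\link{build_calibration_curve}} result.
#' @param target_lfc target log2 fold change; must lie within the curve's
#'   observed lfc range.
#' @return the interpolated spike fraction r_star.
#' @export
invert_calibration <- function(curve, target_lfc) {
  lfc <- curve$lfc; r <- curve$r
  if (anyNA(lfc)) stop_fmt("calibration curve contains NA fold changes")
  if (target_lfc < min(lfc) || target_lfc > max(lfc))
    stop_fmt(paste0("target lfc %.3f outside curve range [%.3f, %.3f]; ",
                    "extend r_grid"), target_lfc, min(lfc), max(lfc))
  for (i in seq_len(length(r) - 1L)) {
    lo <- lfc[i]; hi <- lfc[i + 1L]
    if ((lo - target_lfc) * (hi - target_lfc) <= 0) {
      if (hi == lo) return(r[i])
      return(r[i] + (target_lfc - lo) / (hi - lo) * (r[i + 1L] - r[i]))
    }
  }
  # target equals an endpoint value not bracketed by any interval
  r[which.min(abs(lfc - target_lfc))]
}
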