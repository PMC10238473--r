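#' Percentile segmentation of spots into tissue compartments
#'
#' Labels each spot as fibrotic niche, hepatocyte or other from two gene-set
#' summary scores.  Fibrotic-niche spots are at or above the
#' \code{ecm_hi_pct} percentile of the ECM score and at or below the
#' \code{hep_lo_pct} percentile of the hepatocyte score; hepatocyte spots are
#' at or above the \code{hep_hi_pct} percentile of the hepatocyte score and
#' at or below the \code{ecm_lo_pct} percentile of the ECM score.  Defaults
#' are (85, 15, 20, 80).  Percentiles are computed within each sample (linear
#' interpolation, \code{\link[stats]{quantile}} type 7), since samples differ
#' in depth and composition and compartment fractions are reported per
#' sample.  Ties at a threshold are included per the at-or-above / at-or-below
#' rules; the degenerate case of a score that is constant within a sample
#' makes the high-ECM/low-hepatocyte conjunction unsatisfiable and yields an
#' empty niche there.
#'
#' @param spots a \code{spot_dataset} (used for spot/sample bookkeeping).
#' @param hep_score,ecm_score \code{summary_score} objects computed on the
#'   same spots (hepatocyte and extracellular-matrix scores).
#' @param params named list overriding any of \code{ecm_hi_pct} (85),
#'   \code{hep_lo_pct} (15), \code{hep_hi_pct} (20), \code{ecm_lo_pct} (80).
#' @return object of class \code{segmentation}: list with \code{labels}
#'   (factor niche/hepatocyte/other named by spot id), \code{params} and
#'   \code{thresholds} (per-sample threshold values).
#' @export
segment_spots <- function(spots, hep_score, ecm_score, params = list()) {
  stopifnot(inherits(spots, "spot_dataset"))
  p <- modifyList(list(ecm_hi_pct = 85, hep_lo_pct = 15,
                       hep_hi_pct = 20, ecm_lo_pct = 80), params)
  hep <- if (inherits(hep_score, "summary_score")) hep_score$values else hep_score
  ecm <- if (inherits(ecm_score, "summary_score")) ecm_score$values else ecm_score
  n <- ncol(spots$counts)
  if (length(hep) != n || length(ecm) != n)
    stop_fmt("scores (%d, %d values) must cover all %d spots",
             length(hep), length(ecm), n)
  sample_id <- spots$spot_meta$sample_id
  labels <- rep("other", n)
  thr <- NULL
  for (s in unique(sample_id)) {
    i <- which(sample_id == s)
    qe <- quantile(ecm[i], c(p$ecm_hi_pct, p$ecm_lo_pct) / 100, names = FALSE)
    qh <- quantile(hep[i], c(p$hep_lo_pct, p$hep_hi_pct) / 100, names = FALSE)
    degenerate_e <- diff(range(ecm[i])) == 0
    degenerate_h <- diff(range(hep[i])) == 0
    niche <- if (degenerate_e && degenerate_h) rep(FALSE, length(i)) else
      ecm[i] >= qe[1] & hep[i] <= qh[1]
    hepat <- !niche & hep[i] >= qh[2] & ecm[i] <= qe[2]
    labels[i][niche] <- "niche"
    labels[i][hepat] <- "hepatocyte"
    if (!any(niche))
      warn_fmt("sample %s: empty fibrotic niche under current thresholds", s)
    thr <- rbind(thr, data.frame(sample_id = s, ecm_hi = qe[1], ecm_lo = qe[2],
                                 hep_lo = qh[1], hep_hi = qh[2]))
  }
  out <- list(labels = factor(setNames(labels, spots$spot_meta$spot_id),
                              levels = c("niche", "hepatocyte", "other")),
              params = p, thresholds = thr)
  class(out) <- "segmentation"
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation of", length(x$labels), "spots:\n")
  print(table(x$labels))
  invisible(x)
}
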