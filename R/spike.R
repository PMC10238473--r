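#' Specify a fractional spike-in
#'
#' A spike-in raises one gene's counts inside one tissue compartment: every
#' spot of the target class in sample i gains \code{r} times the median of
#' the gene's unmodified counts over that class in sample i.  The fraction
#' \code{r} is the knob that translates a bulk-tissue effect size into a
#' compartment-level one.
#'
#' @param gene gene id.
#' @param r non-negative spike-in fraction.
#' @param target_class "niche" or "hepatocyte".
#' @return object of class \code{spike_spec}.
#' @export
spike_spec <- function(gene, r, target_class = c("niche", "hepatocyte")) {
  target_class <- match.arg(target_class)
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop_fmt("spike fraction r must be a single non-negative number")
  structure(list(gene = gene, r = r, target_class = target_class),
            class = "spike_spec")
}

#' Apply a fractional spike-in to a spot dataset
#'
#' For each sample, every spot of the target class gains
#' \code{round(r * median(gene counts over target-class spots of that
#' sample))}, rounded half-up so downstream count models receive integers
#' (\code{integer_counts = FALSE} keeps the fractional increment for
#' sensitivity checks).  The median is taken over the unmodified counts; all
#' other genes and all other spots are untouched.  Samples with no
#' target-class spot are skipped with a warning.
#'
#' @param spots a \code{spot_dataset}.
#' @param spec a \code{\link{spike_spec}}.
#' @param labels a \code{\link{segment_spots}} result aligned to
#'   \code{spots}, or a character/factor vector of per-spot class labels.
#' @param integer_counts round the increment to the nearest integer
#'   (default TRUE).
#' @return the spiked \code{spot_dataset}.
#' @export
apply_spike <- function(spots, spec, labels, integer_counts = TRUE) {
  stopifnot(inherits(spots, "spot_dataset"), inherits(spec, "spike_spec"))
  lab <- if (inherits(labels, "segmentation")) labels$labels else labels
  if (length(lab) != ncol(spots$counts))
    stop_fmt("labels (%d) must cover all %d spots", length(lab),
             ncol(spots$counts))
  if (!spec$gene %in% rownames(spots$counts))
    stop_fmt("gene %s not present in the dataset", spec$gene)
  if (spec$r == 0) return(spots)
  out <- spots
  for (s in unique(spots$spot_meta$sample_id)) {
    idx <- which(spots$spot_meta$sample_id == s & lab == spec$target_class)
    if (!length(idx)) {
      warn_fmt("sample %s has no %s spots; skipped", s, spec$target_class)
      next
    }
    inc <- spec$r * median(spots$counts[spec$gene, idx])
    if (integer_counts) inc <- round_half_up(inc)
    out$counts[spec$gene, idx] <- out$counts[spec$gene, idx] + inc
  }
  out
}

#' Pseudobulk: sum spot counts per sample
#'
#' Sums read counts across spots within each sample to obtain "bulk" tissue.
#' Optionally restricted to one segmented compartment.
#'
#' @param spots a \code{spot_dataset}.
#' @param labels optional \code{segmentation} (or label vector) used with
#'   \code{class}.
#' @param class optional compartment name; only spots of this class are
#'   summed.  Default: all spots.
#' @return integer matrix genes x samples.
#' @export
pseudobulk <- function(spots, labels = NULL, class = NULL) {
  stopifnot(inherits(spots, "spot_dataset"))
  keep <- rep(TRUE, ncol(spots$counts))
  if (!is.null(class)) {
    if (is.null(labels)) stop_fmt("class restriction requires labels")
    lab <- if (inherits(labels, "segmentation")) labels$labels else labels
    keep <- as.character(lab) == class
  }
  sample_id <- factor(spots$spot_meta$sample_id)
  out <- t(rowsum(t(spots$counts[, keep, drop = FALSE]),
                  droplevels(sample_id[keep])))
  storage.mode(out) <- "double"
  out
}
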