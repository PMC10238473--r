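#' Number of spots aggregated to mimic an ROI diameter
#'
#' The amount of material captured by a region of illumination scales with
#' tissue area, which is quadratic in diameter, so a D-um ROI is mimicked by
#' aggregating \code{round((D / base)^2)} base spots.  The supported GeoMx
#' diameters 80, 110 and 165 um map to 2, 4 and 9 spots of 55 um.
#'
#' @param diameter_um ROI diameter in micrometres (must be >= base).
#' @param base_diameter_um base spot diameter (default 55).
#' @return integer spot count.
#' @examples
#' diameter_to_spot_count(165)  # 9
#' @export
diameter_to_spot_count <- function(diameter_um, base_diameter_um = 55) {
  if (any(diameter_um < base_diameter_um))
    stop_fmt("diameter (%g um) must be at least the base spot diameter (%g um)",
             min(diameter_um), base_diameter_um)
  as.integer(round_half_up((diameter_um / base_diameter_um)^2))
}

#' Simulation condition for one power-grid cell
#'
#' @param endpoint "primary" (hepatocyte compartment) or "secondary"
#'   (fibrotic niche).
#' @param n_patients_per_group patients per group (>= 2).
#' @param n_rois_per_patient ROIs per patient (>= 1).
#' @param roi_diameter_um one of 80, 110, 165.
#' @param spike the \code{\link{spike_spec}} defining the endpoint gene,
#'   fraction and target class.
#' @return object of class \code{roi_condition}.
#' @export
roi_condition <- function(endpoint = c("primary", "secondary"),
                          n_patients_per_group, n_rois_per_patient,
                          roi_diameter_um, spike) {
  endpoint <- match.arg(endpoint)
  if (!roi_diameter_um %in% c(80, 110, 165))
    stop_fmt("roi_diameter_um must be one of 80, 110, 165")
  if (n_patients_per_group < 2)
    stop_fmt("need >= 2 patients per group")
  if (n_rois_per_patient < 1)
    stop_fmt("need >= 1 ROI per patient")
  stopifnot(inherits(spike, "spike_spec"))
  structure(list(endpoint = endpoint,
                 n_patients_per_group = as.integer(n_patients_per_group),
                 n_rois_per_patient = as.integer(n_rois_per_patient),
                 roi_diameter_um = roi_diameter_um, spike = spike),
            class = "roi_condition")
}

condition_label <- function(cond) {
  paste(cond$endpoint, cond$n_patients_per_group, cond$n_rois_per_patient,
        cond$roi_diameter_um, cond$spike$gene, cond$spike$r,
        cond$spike$target_class, sep = "|")
}

# precompute per-sample coordinates, 4-neighbour adjacency (local indices)
# and eligibility for ROI draws
roi_pool <- function(pool, k) {
  samples <- unique(pool$spot_meta$sample_id)
  per <- lapply(samples, function(s) {
    i <- which(pool$spot_meta$sample_id == s)
    r <- pool$spot_meta$row[i]; cc <- pool$spot_meta$col[i]
    key <- r * 100000 + cc
    nbr <- cbind(match(key + 1, key), match(key - 1, key),
                 match(key + 100000, key), match(key - 100000, key))
    list(idx = i, row = r, col = cc, nbr = nbr)
  })
  names(per) <- samples
  eligible <- samples[vapply(per, function(x) length(x$idx) >= k, logical(1))]
  if (!length(eligible))
    stop_fmt("no sample contains %d spots of the requested class", k)
  list(per = per, eligible = eligible)
}

# one ROI: grid-adjacent same-sample patch of k spots grown from a random
# seed; when the patch cannot grow (thin compartments), fall back to the k
# nearest same-class spots by grid distance
draw_roi_spots <- function(pp, k) {
  s <- if (length(pp$eligible) == 1L) pp$eligible else sample(pp$eligible, 1L)
  info <- pp$per[[s]]
  m <- length(info$idx)
  seed <- sample.int(m, 1L)
  if (k == 1L) return(list(sample_id = s, local = seed, idx = info$idx[seed]))
  in_patch <- rep(FALSE, m)
  in_patch[seed] <- TRUE
  sel <- seed
  frontier <- info$nbr[seed, ]
  frontier <- frontier[!is.na(frontier)]
  while (length(sel) < k) {
    frontier <- frontier[!in_patch[frontier]]
    if (!length(frontier)) break
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    in_patch[nxt] <- TRUE
    sel <- c(sel, nxt)
    nn <- info$nbr[nxt, ]
    frontier <- c(frontier, nn[!is.na(nn)])
  }
  if (length(sel) < k) {                    # fallback: k nearest to the seed
    d <- (info$row - info$row[seed])^2 + (info$col - info$col[seed])^2
    sel <- order(d)[seq_len(k)]
  }
  list(sample_id = s, local = sel, idx = info$idx[sel])
}

#' Draw synthetic ROIs from a class-restricted spot pool
#'
#' Each ROI is the gene-wise sum of counts over k distinct spots of one
#' sample, chosen as a grid-adjacent patch grown from a random seed spot
#' (falling back to the k nearest same-class spots when the patch cannot
#' grow, as happens in thin fibrotic-niche structures).  ROIs are drawn
#' independently, so a spot may be reused across ROIs -- the pool acts as a
#' population that is resampled.
#'
#' @param pool a \code{spot_dataset} restricted to a single tissue class
#'   (see \code{\link{restrict_spots}}).
#' @param k spots per ROI (see \code{\link{diameter_to_spot_count}}).
#' @param n_rois number of ROIs to draw.
#' @return list with \code{counts} (genes x n_rois), \code{meta}
#'   (source_sample_id, n_spots per ROI) and \code{provenance} (list of spot
#'   column indices into the pool).
#' @export
sample_rois <- function(pool, k, n_rois) {
  stopifnot(inherits(pool, "spot_dataset"))
  pp <- roi_pool(pool, k)
  prov <- vector("list", n_rois)
  counts <- matrix(0, nrow(pool$counts), n_rois,
                   dimnames = list(rownames(pool$counts),
                                   sprintf("ROI%03d", seq_len(n_rois))))
  src <- character(n_rois)
  for (j in seq_len(n_rois)) {
    d <- draw_roi_spots(pp, k)
    prov[[j]] <- d$idx
    src[j] <- d$sample_id
    counts[, j] <- if (length(d$idx) == 1L) pool$counts[, d$idx] else
      rowSums(pool$counts[, d$idx, drop = FALSE])
  }
  list(counts = counts,
       meta = data.frame(source_sample_id = src, n_spots = k),
       provenance = prov)
}

#' Assemble a synthetic GeoMx ROI dataset for one condition
#'
#' Draws \code{n_patients_per_group * n_rois_per_patient} ROIs per group --
#' the control group from the unmodified pool, the spiked group from the
#' spiked pool -- and partitions each group's freshly drawn ROIs into
#' patients with exactly \code{n_rois_per_patient} ROIs each.  No
#' patient-level random effect is planted: the reference spot populations
#' are exchangeable across samples, and the patient partition is the random
#' mechanism.  The gene panel is then restricted to panel members; the
#' endpoint gene and background probes are always retained.
#'
#' @param cond a \code{\link{roi_condition}}.
#' @param pool_control,pool_spiked class-restricted \code{spot_dataset}s
#'   sharing the same gene axis.
#' @return object of class \code{roi_dataset}: list with integer
#'   \code{counts} (genes x ROIs), \code{roi_meta} (roi_id, patient_id,
#'   group, tissue_class, diameter_um, n_spots_aggregated,
#'   source_sample_id) and \code{gene_meta}.
#' @export
assemble_dataset <- function(cond, pool_control, pool_spiked) {
  stopifnot(inherits(cond, "roi_condition"))
  if (!identical(rownames(pool_control$counts), rownames(pool_spiked$counts)))
    stop_fmt("control and spiked pools must share the gene axis")
  k <- diameter_to_spot_count(cond$roi_diameter_um)
  n_per_group <- cond$n_patients_per_group * cond$n_rois_per_patient
  ctrl <- sample_rois(pool_control, k, n_per_group)
  spik <- sample_rois(pool_spiked, k, n_per_group)
  counts <- cbind(ctrl$counts, spik$counts)
  colnames(counts) <- sprintf("ROI%03d", seq_len(2L * n_per_group))
  patient <- sprintf("%s%02d", rep(c("C", "T"), each = n_per_group),
                     rep(rep(seq_len(cond$n_patients_per_group),
                             each = cond$n_rois_per_patient), 2))
  roi_meta <- data.frame(
    roi_id = colnames(counts),
    patient_id = patient,
    group = rep(c("control", "spiked"), each = n_per_group),
    tissue_class = cond$spike$target_class,
    diameter_um = cond$roi_diameter_um,
    n_spots_aggregated = k,
    source_sample_id = c(ctrl$meta$source_sample_id,
                         spik$meta$source_sample_id),
    stringsAsFactors = FALSE)
  gm <- pool_control$gene_meta
  keep <- gm$panel_member | gm$background_probe | gm$gene_id == cond$spike$gene
  out <- list(counts = counts[keep, , drop = FALSE],
              roi_meta = roi_meta, gene_meta = gm[keep, , drop = FALSE],
              condition = cond)
  class(out) <- "roi_dataset"
  out
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat("roi_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "ROIs (",
      x$roi_meta$diameter_um[1], "um,", x$roi_meta$n_spots_aggregated[1],
      "spots each )\n")
  print(table(x$roi_meta$group))
  invisible(x)
}

#' Remove ROIs at random without losing any patient entirely
#'
#' Emulates technical quality-control failure: a uniformly random subset of
#' \code{n_remove} ROIs is removed, rejection-sampled so that every patient
#' retains at least one ROI.
#'
#' @param ds a \code{roi_dataset}.
#' @param n_remove number of ROIs to drop.
#' @param max_tries rejection-sampling attempts before giving up.
#' @return the reduced \code{roi_dataset}.
#' @export
apply_dropout <- function(ds, n_remove, max_tries = 1000L) {
  stopifnot(inherits(ds, "roi_dataset"))
  n <- ncol(ds$counts)
  if (n_remove == 0) return(ds)
  n_patients <- length(unique(ds$roi_meta$patient_id))
  if (n_remove >= n || n - n_remove < n_patients)
    stop_fmt(paste0("cannot remove %d of %d ROIs while keeping >= 1 ROI ",
                    "for each of %d patients"), n_remove, n, n_patients)
  for (t in seq_len(max_tries)) {
    drop <- sample.int(n, n_remove)
    left <- table(ds$roi_meta$patient_id[-drop])
    if (length(left) == n_patients && all(left >= 1)) {
      out <- ds
      out$counts <- ds$counts[, -drop, drop = FALSE]
      out$roi_meta <- ds$roi_meta[-drop, , drop = FALSE]
      rownames(out$roi_meta) <- NULL
      return(out)
    }
  }
  stop_fmt("dropout constraint unsatisfiable after %d attempts", max_tries)
}

#' Append a composite gene summing a gene set's raw counts
#'
#' Adds one row holding the column-wise sum of the member genes' raw counts
#' (a cheap instrument-side approximation of a gene-set summary score).  The
#' member rows are retained; the composite is flagged in \code{gene_meta}
#' and excluded from library-size computations.
#'
#' @param ds a \code{roi_dataset} or \code{spot_dataset}.
#' @param gene_set character vector of member gene ids (non-empty, present).
#' @param name id of the composite row (default "composite").
#' @return the dataset with one extra count row.
#' @export
sum_gene_set <- function(ds, gene_set, name = "composite") {
  if (!length(gene_set)) stop_fmt("gene set is empty")
  missing <- setdiff(gene_set, rownames(ds$counts))
  if (length(missing))
    stop_fmt("%d gene(s) absent from dataset (e.g. %s)", length(missing),
             missing[1L])
  comp <- if (length(gene_set) == 1L) ds$counts[gene_set, ] else
    colSums(ds$counts[gene_set, , drop = FALSE])
  out <- ds
  out$counts <- rbind(ds$counts, matrix(comp, 1,
                                        dimnames = list(name, NULL)))
  gm_new <- data.frame(gene_id = name, marker_set = NA_character_,
                       panel_member = FALSE, background_probe = FALSE,
                       composite = TRUE, stringsAsFactors = FALSE)
  if (!"composite" %in% names(out$gene_meta)) out$gene_meta$composite <- FALSE
  out$gene_meta <- rbind(out$gene_meta[names(gm_new)], gm_new)
  rownames(out$gene_meta) <- NULL
  out
}
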