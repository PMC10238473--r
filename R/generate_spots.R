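#' Generate a synthetic Visium-like spot dataset
#'
#' Draws negative binomial spot counts on a regular grid for each tissue
#' sample.  Compartments (fibrotic niche, hepatocyte, other) are planted as
#' contiguous blobs grown from random seed spots, so that neighbour
#' aggregation into larger ROIs is meaningful; the blob sizes enforce the
#' configured compartment fractions (with +/-10 percent per-sample jitter).
#' Counts for gene g in a spot of class c are
#' \code{NB(mean = L_spot * rho[g, c], size = theta)} where the per-spot
#' library size \code{L_spot} is log-normal and \code{rho[, c]} is the
#' class-specific relative-expression profile (marker sets are elevated in
#' their home compartment).  Spots are exchangeable given their class: no
#' sample-level expression effect is planted, so within-sample correlations
#' are no stronger than between-sample ones.
#'
#' Background probes are synthetic genes with relative expression at most a
#' tenth of the global median in every class, flagged in \code{gene_meta}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{spot_dataset}: a list with integer
#'   \code{counts} (genes x spots), \code{spot_meta} (spot_id, sample_id,
#'   row, col, true_class), \code{gene_meta} (gene_id, marker_set,
#'   panel_member, background_probe), \code{spot_diameter_um} (55) and
#'   \code{spot_spacing_um} (100).
#' @examples
#' cfg <- sim_config(seed = 7, n_samples = 2, grid_rows = 14, grid_cols = 14,
#'                   n_genes = 80, marker_sets = list(
#'                     hepatocyte = sprintf("G%04d", 1:8),
#'                     ecm = sprintf("G%04d", 9:16),
#'                     mesenchyme = sprintf("G%04d", 17:20),
#'                     lipid = sprintf("G%04d", 21:30),
#'                     cytoskeleton = sprintf("G%04d", 31:40),
#'                     background = sprintf("G%04d", 41:44)))
#' spots <- generate_spot_dataset(cfg)
#' table(spots$spot_meta$true_class)
#' @export
generate_spot_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_spots_sample <- config$grid_rows * config$grid_cols
  if (round(config$niche_fraction * n_spots_sample) < 1 &&
      config$niche_fraction > 0)
    stop_fmt("grid of %d spots is too small to host niche_fraction = %g",
             n_spots_sample, config$niche_fraction)

  rho <- class_profiles_matrix(config)          # genes x 3 (niche, hep, other)
  ids <- gene_ids(config$n_genes)

  spot_meta <- NULL
  count_cols <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    lay <- plant_compartments(config$grid_rows, config$grid_cols,
                              config$niche_fraction,
                              config$hepatocyte_fraction)
    n_spots <- nrow(lay)
    lib <- rlnorm(n_spots, config$libsize_log_mean, config$libsize_log_sd)
    cls_idx <- match(lay$true_class, c("niche", "hepatocyte", "other"))
    mu <- rho[, cls_idx, drop = FALSE] * rep(lib, each = config$n_genes)
    cnt <- matrix(rnbinom(length(mu), size = config$dispersion, mu = mu),
                  nrow = config$n_genes)
    count_cols[[s]] <- cnt
    lay$sample_id <- sprintf("S%02d", s)
    spot_meta <- rbind(spot_meta, lay)
  }
  counts <- do.call(cbind, count_cols)
  spot_meta$spot_id <- sprintf("%s_r%02dc%02d", spot_meta$sample_id,
                               spot_meta$row, spot_meta$col)
  spot_meta <- spot_meta[c("spot_id", "sample_id", "row", "col", "true_class")]
  dimnames(counts) <- list(ids, spot_meta$spot_id)

  gene_meta <- data.frame(gene_id = ids, marker_set = NA_character_,
                          panel_member = TRUE, background_probe = FALSE,
                          composite = FALSE, stringsAsFactors = FALSE)
  for (nm in names(config$marker_sets))
    gene_meta$marker_set[match(config$marker_sets[[nm]], ids)] <- nm
  gene_meta$background_probe <- gene_meta$marker_set %in% "background"
  free <- which(is.na(gene_meta$marker_set))
  n_off <- floor(length(free) * config$panel_nonmember_fraction)
  if (n_off > 0) gene_meta$panel_member[free[seq_len(n_off)]] <- FALSE

  new_spot_dataset(counts, spot_meta, gene_meta)
}

new_spot_dataset <- function(counts, spot_meta, gene_meta,
                             spot_diameter_um = 55, spot_spacing_um = 100) {
  x <- list(counts = counts, spot_meta = spot_meta, gene_meta = gene_meta,
            spot_diameter_um = spot_diameter_um,
            spot_spacing_um = spot_spacing_um)
  class(x) <- "spot_dataset"
  validate_spot_dataset(x)
}

validate_spot_dataset <- function(x) {
  stopifnot(inherits(x, "spot_dataset"))
  check_integer_counts(x$counts)
  if (ncol(x$counts) != nrow(x$spot_meta))
    stop_fmt("spot_dataset: %d count columns but %d spot_meta rows",
             ncol(x$counts), nrow(x$spot_meta))
  if (nrow(x$counts) != nrow(x$gene_meta))
    stop_fmt("spot_dataset: %d count rows but %d gene_meta rows",
             nrow(x$counts), nrow(x$gene_meta))
  key <- paste(x$spot_meta$sample_id, x$spot_meta$row, x$spot_meta$col)
  if (anyDuplicated(key))
    stop_fmt("spot_dataset: duplicated (sample, row, col) coordinates")
  if (anyDuplicated(x$gene_meta$gene_id))
    stop_fmt("spot_dataset: duplicated gene ids")
  invisible(x)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("spot_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "spots in",
      length(unique(x$spot_meta$sample_id)), "samples\n")
  print(table(x$spot_meta$true_class))
  invisible(x)
}

#' Restrict a spot dataset to a subset of spots
#'
#' @param spots a \code{spot_dataset}.
#' @param idx logical or integer spot index (columns of \code{counts}).
#' @return a \code{spot_dataset} with the selected spots.
#' @export
restrict_spots <- function(spots, idx) {
  out <- spots
  out$counts <- spots$counts[, idx, drop = FALSE]
  out$spot_meta <- spots$spot_meta[idx, , drop = FALSE]
  rownames(out$spot_meta) <- NULL
  out
}

# class-specific relative expression profiles, columns (niche, hepatocyte,
# other), each normalized to sum 1 so that a spot's expected total equals its
# library size
class_profiles_matrix <- function(config) {
  n <- config$n_genes
  ids <- gene_ids(n)
  base <- rlnorm(n, 0, 1)
  bg <- match(config$marker_sets$background, ids)
  base[bg] <- median(base) / 20          # background probes: very low
  f <- config$marker_fold
  prof <- default_class_profiles(f)
  if (!is.null(config$class_profiles))
    prof <- modifyList(prof, config$class_profiles)
  mult <- matrix(1, n, 3, dimnames = list(ids, c("niche", "hepatocyte",
                                                 "other")))
  for (nm in setdiff(names(config$marker_sets), "background")) {
    g <- match(config$marker_sets[[nm]], ids)
    mult[g, ] <- matrix(prof[[nm]][c("niche", "hepatocyte", "other")],
                        length(g), 3, byrow = TRUE)
  }
  rho <- base * mult
  sweep(rho, 2, colSums(rho), "/")
}

# multipliers chosen so that percentile segmentation recovers the planted
# classes: ECM-type markers are intermediate in "other" tissue, which places
# the 80th ECM percentile above the hepatocyte compartment's scores
default_class_profiles <- function(f) {
  list(hepatocyte   = c(niche = 0.5, hepatocyte = f,     other = 1),
       lipid        = c(niche = 0.5, hepatocyte = f,     other = 1),
       ecm          = c(niche = 2 * f, hepatocyte = 1,   other = 2),
       mesenchyme   = c(niche = 2 * f, hepatocyte = 1,   other = 2),
       cytoskeleton = c(niche = f,   hepatocyte = 0.5,   other = 1))
}

# contiguous compartment layout on one grid: niche blobs first (thin
# structures, several small seeds), then hepatocyte blobs, remainder "other";
# realized fractions jittered +/-10% around the targets
plant_compartments <- function(rows, cols, niche_frac, hep_frac) {
  n <- rows * cols
  lay <- data.frame(row = rep(seq_len(rows), times = cols),
                    col = rep(seq_len(cols), each = rows),
                    true_class = "other", stringsAsFactors = FALSE)
  n_niche <- round_half_up(n * niche_frac * runif(1, 0.9, 1.1))
  n_hep <- round_half_up(n * hep_frac * runif(1, 0.9, 1.1))
  n_hep <- min(n_hep, n - n_niche)
  assigned <- rep(FALSE, n)
  if (n_niche > 0) {
    niche <- grow_blobs(rows, cols, assigned, n_niche,
                        n_seeds = max(1L, round(n_niche / 12)))
    lay$true_class[niche] <- "niche"
    assigned[niche] <- TRUE
  }
  if (n_hep > 0) {
    hep <- grow_blobs(rows, cols, assigned, n_hep, n_seeds = 4L)
    lay$true_class[hep] <- "hepatocyte"
  }
  lay
}

# seeded random growth over the 4-neighbour lattice
grow_blobs <- function(rows, cols, assigned, target, n_seeds) {
  n <- rows * cols
  taken <- assigned
  sel <- integer(0)
  frontier <- integer(0)
  free0 <- which(!taken)
  seeds <- sample(free0, min(n_seeds, length(free0)))
  for (s in seeds) {
    if (length(sel) >= target) break
    if (taken[s]) next
    taken[s] <- TRUE; sel <- c(sel, s)
    frontier <- c(frontier, neighbours4(s, rows, cols))
  }
  while (length(sel) < target) {
    frontier <- frontier[!taken[frontier]]
    if (!length(frontier)) {               # stuck: restart from any free spot
      free <- which(!taken)
      if (!length(free)) break
      s <- if (length(free) == 1L) free else sample(free, 1L)
      taken[s] <- TRUE; sel <- c(sel, s)
      frontier <- neighbours4(s, rows, cols)
      next
    }
    s <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    taken[s] <- TRUE; sel <- c(sel, s)
    frontier <- c(frontier, neighbours4(s, rows, cols))
  }
  sel
}

neighbours4 <- function(i, rows, cols) {
  r <- (i - 1L) %% rows + 1L
  cc <- (i - 1L) %/% rows + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, i - 1L)
  if (r < rows) out <- c(out, i + 1L)
  if (cc > 1L) out <- c(out, i - rows)
  if (cc < cols) out <- c(out, i + rows)
  out
}
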