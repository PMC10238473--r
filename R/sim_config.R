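#' Configuration for the synthetic spot and bulk-cohort generators
#'
#' Bundles every knob of the synthetic-data module: the Visium-like spot grid
#' (5 tissue samples of 55 um spots at 100 um centre spacing by default), the
#' tissue-compartment layout (a fibrotic-niche compartment covering a few
#' percent of spots and a dominant hepatocyte compartment), per-spot
#' library-size heterogeneity, the negative binomial dispersion, the marker
#' gene sets, and the bulk cohort (28 stable / 15 progressor / 15 regressor
#' subjects with fibrosis stage and NAS covariates and planted
#' opposite-direction gene-set effects).
#'
#' @param seed integer seed; the generators are fully deterministic given the
#'   config.
#' @param n_samples number of tissue samples (default 5).
#' @param grid_rows,grid_cols spot grid dimensions per sample.
#' @param n_genes number of genes.
#' @param niche_fraction target fraction of spots in the fibrotic-niche
#'   compartment (default 0.05; realized per-sample fractions are jittered
#'   within +/-10 percent, landing inside the 2.6--7.1 percent range reported
#'   for NAFLD-range fibrosis when left at the default).
#' @param hepatocyte_fraction target hepatocyte-compartment fraction
#'   (default 0.65, the lower range of literature estimates of hepatocyte
#'   volume fraction).
#' @param libsize_log_mean,libsize_log_sd log-normal parameters of the
#'   per-spot library size (defaults log(4000) and 0.35).
#' @param dispersion negative binomial size parameter theta shared by all
#'   genes (default 2; larger is less overdispersed).
#' @param marker_fold fold elevation of a marker set in its home compartment
#'   (default 4, on the linear scale).
#' @param marker_sets named list of gene-id character vectors with elements
#'   \code{hepatocyte}, \code{ecm}, \code{mesenchyme}, \code{lipid},
#'   \code{cytoskeleton}, \code{background}; must be pairwise disjoint.
#'   \code{NULL} (default) allocates sets of sizes 30/30/20/44/89/20 from the
#'   gene panel (44 lipid and 89 cytoskeleton genes mirror the bulk-screen
#'   set sizes).
#' @param class_profiles optional named list overriding the per-class
#'   expression multipliers of a marker set, each element a numeric vector
#'   with names \code{niche}, \code{hepatocyte}, \code{other}.
#' @param bulk_n_per_group named counts of bulk subjects, names
#'   \code{stable}, \code{progressor}, \code{regressor} (default 28/15/15).
#' @param bulk_effect_log2fc named numeric: planted bulk log2 fold change of
#'   each gene set in progressors vs stable; regressors receive the negated
#'   effect (opposite-direction structure).  Default
#'   \code{c(lipid = -0.42, cytoskeleton = 1.5)}.
#' @param bulk_libsize_log_mean,bulk_libsize_log_sd log-normal parameters of
#'   bulk subject library sizes.
#' @param bulk_dispersion negative binomial size for bulk counts (default 8;
#'   subject-to-subject variation is milder than spot-to-spot).
#' @param panel_nonmember_fraction fraction of non-marker genes flagged as
#'   absent from the measurement panel (default 0.1).
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_samples = 2, grid_rows = 12, grid_cols = 12,
#'                   n_genes = 60)
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 5L,
                       grid_rows = 40L,
                       grid_cols = 40L,
                       n_genes = 1000L,
                       niche_fraction = 0.05,
                       hepatocyte_fraction = 0.65,
                       libsize_log_mean = log(4000),
                       libsize_log_sd = 0.35,
                       dispersion = 2,
                       marker_fold = 4,
                       marker_sets = NULL,
                       class_profiles = NULL,
                       bulk_n_per_group = c(stable = 28L, progressor = 15L,
                                            regressor = 15L),
                       bulk_effect_log2fc = c(lipid = -0.42,
                                              cytoskeleton = 1.5),
                       bulk_libsize_log_mean = log(1e6),
                       bulk_libsize_log_sd = 0.25,
                       bulk_dispersion = 8,
                       panel_nonmember_fraction = 0.1) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              n_genes = as.integer(n_genes),
              niche_fraction = niche_fraction,
              hepatocyte_fraction = hepatocyte_fraction,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              dispersion = dispersion, marker_fold = marker_fold,
              marker_sets = marker_sets, class_profiles = class_profiles,
              bulk_n_per_group = bulk_n_per_group,
              bulk_effect_log2fc = bulk_effect_log2fc,
              bulk_libsize_log_mean = bulk_libsize_log_mean,
              bulk_libsize_log_sd = bulk_libsize_log_sd,
              bulk_dispersion = bulk_dispersion,
              panel_nonmember_fraction = panel_nonmember_fraction)
  class(cfg) <- "sim_config"
  if (is.null(cfg$marker_sets))
    cfg$marker_sets <- default_marker_sets(cfg$n_genes)
  validate_sim_config(cfg)
  cfg
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# default marker-set allocation over the gene panel; lipid 44 and
# cytoskeleton 89 match the bulk-screen gene-set sizes
default_marker_sets <- function(n_genes) {
  sizes <- c(hepatocyte = 30L, ecm = 30L, mesenchyme = 20L, lipid = 44L,
             cytoskeleton = 89L, background = 20L)
  if (n_genes < sum(sizes) + 50L)
    stop_fmt(paste0("n_genes = %d is too small for the default marker sets ",
                    "(need >= %d); pass explicit marker_sets"),
             n_genes, sum(sizes) + 50L)
  ids <- gene_ids(n_genes)
  out <- list(); at <- 0L
  for (nm in names(sizes)) {
    out[[nm]] <- ids[(at + 1L):(at + sizes[[nm]])]
    at <- at + sizes[[nm]]
  }
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (f in c("n_samples", "grid_rows", "grid_cols", "n_genes"))
    if (!is_count(cfg[[f]])) stop_fmt("sim_config: %s must be a count >= 1", f)
  if (cfg$niche_fraction < 0 || cfg$niche_fraction > 1 ||
      cfg$hepatocyte_fraction < 0 || cfg$hepatocyte_fraction > 1)
    stop_fmt("sim_config: compartment fractions must lie in [0, 1]")
  if (cfg$niche_fraction + cfg$hepatocyte_fraction > 1)
    stop_fmt("sim_config: niche_fraction + hepatocyte_fraction must be <= 1")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    stop_fmt("sim_config: dispersion (NB size theta) must be > 0")
  ms <- cfg$marker_sets
  need <- c("hepatocyte", "ecm", "mesenchyme", "lipid", "cytoskeleton",
            "background")
  if (!all(need %in% names(ms)))
    stop_fmt("sim_config: marker_sets must contain: %s",
             paste(need, collapse = ", "))
  all_ids <- unlist(ms, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop_fmt("sim_config: marker sets must be pairwise disjoint (duplicate: %s)",
             all_ids[duplicated(all_ids)][1L])
  if (!all(all_ids %in% gene_ids(cfg$n_genes)))
    stop_fmt("sim_config: marker sets reference gene ids outside the panel")
  gn <- cfg$bulk_n_per_group
  if (!all(c("stable", "progressor", "regressor") %in% names(gn)) ||
      any(gn < 1))
    stop_fmt("sim_config: bulk_n_per_group needs >= 1 subject in each of %s",
             "stable/progressor/regressor")
  if (!all(names(cfg$bulk_effect_log2fc) %in% names(ms)))
    stop_fmt("sim_config: bulk_effect_log2fc names must be marker-set names")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples of", x$grid_rows, "x", x$grid_cols,
      "spots,", x$n_genes, "genes\n")
  cat("  compartments: niche", x$niche_fraction, "/ hepatocyte",
      x$hepatocyte_fraction, "; theta =", x$dispersion, "\n")
  cat("  bulk cohort:", paste(names(x$bulk_n_per_group), x$bulk_n_per_group,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
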