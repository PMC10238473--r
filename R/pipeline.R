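#' Default end-to-end pipeline configuration
#'
#' A small, fully specified configuration for \code{\link{run_pipeline}}:
#' simulate spot and bulk data, discover endpoints in the bulk cohort,
#' calibrate spike-in fractions on the spot data, and run a demonstration
#' power grid.  All sizes are deliberately modest so that the demo completes
#' in well under a minute; scale the fields up for a real planning run.
#'
#' @param master_seed integer master seed.
#' @param output_dir output directory.
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(master_seed = 1L, output_dir = "roipower_run") {
  cfg <- list(
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    simulate = list(n_samples = 3L, grid_rows = 24L, grid_cols = 24L,
                    n_genes = 300L),
    discover = list(corr_threshold = 0.1),
    calibrate = list(r_grid = seq(0, 4, by = 0.25)),
    power = list(alpha = 0.025, n_reps = 20L, methods = "wald_glmm",
                 n_patients = c(4L, 8L), n_rois = 2L, diameter_um = 165),
    sensitivity = list(n_remove = 4L))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full planning pipeline
#'
#' Executes simulate -> discover-endpoints -> calibrate -> power-grid ->
#' dropout-sensitivity in order, persisting each stage's outputs as CSV (or
#' the MatrixMarket triplet for spot data) under \code{config$output_dir},
#' plus a \code{manifest.json} recording the master seed, alpha, package
#' version and a hash of the configuration.  Reruns with the same
#' configuration reproduce identical result tables.
#'
#' Endpoints are chosen from the bulk screen: among selected candidates in
#' the lipid set, the gene with the strongest regressor effect becomes the
#' primary (hepatocyte-compartment) endpoint; the strongest progressor
#' candidate in the cytoskeleton set becomes the secondary (fibrotic-niche)
#' endpoint.  Their bulk log2 fold changes are inverted on the calibration
#' curves to obtain the spike fractions used in the power grid.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the output directory, invisibly; stage results are also returned
#'   as the attribute \code{"results"}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
               name, conditionMessage(e), out))
  }

  ## simulate
  sim <- config$simulate
  scfg <- sim_config(seed = config$master_seed, n_samples = sim$n_samples,
                     grid_rows = sim$grid_rows, grid_cols = sim$grid_cols,
                     n_genes = sim$n_genes,
                     marker_sets = scaled_marker_sets(sim$n_genes))
  spots <- stage("simulate", generate_spot_dataset(scfg))
  bulk <- stage("simulate", generate_bulk_cohort(scfg))
  write_spot_dataset(spots, file.path(out, "spots"))
  write_bulk_cohort(bulk, file.path(out, "bulk"))

  ## discover endpoints in bulk
  norm <- stage("discover", normalize_counts(bulk$counts))
  screen <- stage("discover",
                  candidate_gene_screen(norm, bulk$subject_meta))
  utils::write.csv(screen, file.path(out, "screen.csv"), row.names = FALSE)
  pick <- function(set, col) {
    cand <- screen[screen$selected & screen$gene_id %in%
                     scfg$marker_sets[[set]], ]
    if (!nrow(cand)) cand <- screen[screen$gene_id %in%
                                      scfg$marker_sets[[set]], ]
    cand$gene_id[which.max(abs(cand[[col]]))]
  }
  primary_gene <- stage("discover", pick("lipid", "lfc_regr"))
  secondary_gene <- stage("discover", pick("cytoskeleton", "lfc_prog"))
  target_primary <- abs(screen$lfc_regr[screen$gene_id == primary_gene])
  target_secondary <- abs(screen$lfc_prog[screen$gene_id == secondary_gene])

  ## segment spots and calibrate
  snorm <- normalize_counts(spots$counts, method = "libsize")
  hep <- kuppe_score(snorm, scfg$marker_sets$hepatocyte, name = "hepatocyte")
  ecm <- kuppe_score(snorm, scfg$marker_sets$ecm, name = "ecm")
  seg <- stage("calibrate",
               suppressWarnings(segment_spots(spots, hep, ecm)))
  utils::write.csv(data.frame(spot_id = names(seg$labels),
                              label = as.character(seg$labels)),
                   file.path(out, "segmentation.csv"), row.names = FALSE)
  cal <- list(
    primary = stage("calibrate",
                    build_calibration_curve(spots, seg, primary_gene,
                                            "hepatocyte",
                                            config$calibrate$r_grid)),
    secondary = stage("calibrate",
                      build_calibration_curve(spots, seg, secondary_gene,
                                              "niche",
                                              config$calibrate$r_grid)))
  utils::write.csv(do.call(rbind, lapply(names(cal), function(nm)
    data.frame(endpoint = nm, cal[[nm]]))),
    file.path(out, "calibration.csv"), row.names = FALSE)
  clamp <- function(curve, t) min(max(t, min(curve$lfc)), max(curve$lfc))
  r_primary <- invert_calibration(cal$primary,
                                  clamp(cal$primary, target_primary))
  r_secondary <- invert_calibration(cal$secondary,
                                    clamp(cal$secondary, target_secondary))

  ## power grid on the primary endpoint
  pw <- config$power
  spike <- spike_spec(primary_gene, r_primary, "hepatocyte")
  hep_idx <- seg$labels == "hepatocyte"
  pool_c <- restrict_spots(spots, hep_idx)
  pool_s <- restrict_spots(apply_spike(spots, spike, seg), hep_idx)
  cfg_run <- run_config(alpha = pw$alpha, n_reps = pw$n_reps,
                        methods = pw$methods, seed = config$master_seed)
  conds <- lapply(pw$n_patients, function(np)
    roi_condition("primary", np, pw$n_rois, pw$diameter_um, spike))
  grid <- stage("power", run_grid(conds,
                                  list(primary = list(control = pool_c,
                                                      spiked = pool_s)),
                                  cfg_run))
  grid$master_seed <- config$master_seed
  utils::write.csv(grid, file.path(out, "power.csv"), row.names = FALSE)

  ## dropout sensitivity on the first condition
  sens <- stage("sensitivity",
                dropout_sensitivity(conds[[1]], pool_c, pool_s, cfg_run,
                                    config$sensitivity$n_remove))
  sens$master_seed <- config$master_seed
  utils::write.csv(sens, file.path(out, "sensitivity.csv"), row.names = FALSE)

  ## manifest
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(master_seed = config$master_seed,
                   alpha = pw$alpha,
                   primary_endpoint = list(gene = primary_gene,
                                           target_lfc = target_primary,
                                           r_star = r_primary),
                   secondary_endpoint = list(gene = secondary_gene,
                                             target_lfc = target_secondary,
                                             r_star = r_secondary),
                   config_hash = unname(tools::md5sum(cfg_json)),
                   package_version =
                     as.character(utils::packageVersion("roipower")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(screen = screen, segmentation = seg, calibration = cal,
              power = grid, sensitivity = sens, manifest = manifest)
  structure(invisible(out), results = res)
}

# marker sets scaled down for small demo panels
scaled_marker_sets <- function(n_genes) {
  sizes <- c(hepatocyte = 15L, ecm = 15L, mesenchyme = 8L, lipid = 20L,
             cytoskeleton = 30L, background = 8L)
  if (n_genes >= 283L) return(NULL)          # full-size defaults apply
  if (n_genes < sum(sizes) + 20L)
    stop_fmt("pipeline demo needs n_genes >= %d", sum(sizes) + 20L)
  ids <- gene_ids(n_genes)
  out <- list(); at <- 0L
  for (nm in names(sizes)) {
    out[[nm]] <- ids[(at + 1L):(at + sizes[[nm]])]
    at <- at + sizes[[nm]]
  }
  out
}
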