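# shared fixtures, memoized so expensive synthetic pools are built once per run

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# marker sets sized for small gene panels
tiny_marker_sets <- function(n_genes,
                             sizes = c(hepatocyte = 10L, ecm = 10L,
                                       mesenchyme = 5L, lipid = 10L,
                                       cytoskeleton = 12L, background = 5L)) {
  ids <- sprintf("G%04d", seq_len(n_genes))
  out <- list(); at <- 0L
  for (nm in names(sizes)) {
    out[[nm]] <- ids[(at + 1L):(at + sizes[[nm]])]
    at <- at + sizes[[nm]]
  }
  out
}

small_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_samples = 3L, grid_rows = 20L, grid_cols = 20L,
             n_genes = 150L, marker_sets = tiny_marker_sets(150L), ...)
}

small_spots <- function() {
  memo_fixture("small_spots", function() generate_spot_dataset(small_config()))
}

# the reference-scale fixture used for calibration and power checks:
# 5 samples of 30 x 30 spots, 300 genes, default compartment fractions
ref_config <- function() sim_config(seed = 11L, n_samples = 5L,
                                    grid_rows = 30L, grid_cols = 30L,
                                    n_genes = 300L)

ref_spots <- function() {
  memo_fixture("ref_spots", function() generate_spot_dataset(ref_config()))
}

ref_segmentation <- function() {
  memo_fixture("ref_segmentation", function() {
    spots <- ref_spots()
    cfg <- ref_config()
    snorm <- normalize_counts(spots$counts, method = "libsize")
    segment_spots(spots,
                  kuppe_score(snorm, cfg$marker_sets$hepatocyte,
                              name = "hepatocyte"),
                  kuppe_score(snorm, cfg$marker_sets$ecm, name = "ecm"))
  })
}

ref_hep_pool <- function() {
  memo_fixture("ref_hep_pool", function()
    restrict_spots(ref_spots(), ref_segmentation()$labels == "hepatocyte"))
}

ref_niche_pool <- function() {
  memo_fixture("ref_niche_pool", function()
    restrict_spots(ref_spots(), ref_segmentation()$labels == "niche"))
}

ref_endpoint_gene <- function() ref_config()$marker_sets$lipid[1L]

ref_spiked_hep_pool <- function(r = 0.43) {
  name <- paste0("ref_spiked_hep_pool_", r)
  memo_fixture(name, function() {
    spk <- spike_spec(ref_endpoint_gene(), r, "hepatocyte")
    restrict_spots(apply_spike(ref_spots(), spk, ref_segmentation()),
                   ref_segmentation()$labels == "hepatocyte")
  })
}

# hand-built tiny spot dataset for exact-arithmetic checks
toy_spots <- function(counts, sample_id, true_class) {
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%04d", seq_len(nrow(counts)))
  meta <- data.frame(
    spot_id = sprintf("spot%02d", seq_len(n)), sample_id = sample_id,
    row = rep(1L, n), col = seq_len(n), true_class = true_class,
    stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = rownames(counts), marker_set = NA_character_,
                   panel_member = TRUE, background_probe = FALSE,
                   composite = FALSE, stringsAsFactors = FALSE)
  colnames(counts) <- meta$spot_id
  roipower:::new_spot_dataset(counts, meta, gm)
}

as_norm <- function(values) {
  structure(list(values = values, size_factors = rep(1, ncol(values)),
                 pseudocount = 1, method = "median_ratios"),
            class = "normalized_matrix")
}
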