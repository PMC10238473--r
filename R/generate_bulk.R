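#' Generate a synthetic bulk RNA-seq cohort
#'
#' Emulates a longitudinal fibrosis cohort stratified by two-year outcome:
#' by default 28 subjects with stable fibrosis stage, 15 fibrosis regressors
#' and 15 fibrosis progressors, each with a baseline fibrosis stage (F1--F4)
#' and NAFLD activity score (NAS, 0--8).  Gene-set effects are planted with
#' opposite directions in progressors and regressors: a set with planted
#' log2 fold change \code{d} (progressor vs stable) is scaled by
#' \code{2^d} in progressors and \code{2^-d} in regressors.
#'
#' @param config a \code{\link{sim_config}}; relevant fields are
#'   \code{bulk_n_per_group}, \code{bulk_effect_log2fc},
#'   \code{bulk_libsize_log_mean/sd} and \code{bulk_dispersion}.
#' @return an object of class \code{bulk_cohort}: list with integer
#'   \code{counts} (genes x subjects) and \code{subject_meta}
#'   (subject_id, group, fibrosis_stage, NAS).
#' @examples
#' cohort <- generate_bulk_cohort(sim_config(seed = 3))
#' table(cohort$subject_meta$group)
#' @export
generate_bulk_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "bulk_cohort"))
  gn <- config$bulk_n_per_group
  if (any(gn < 1)) stop_fmt("bulk_n_per_group: every group needs >= 1 subject")
  groups <- factor(rep(c("stable", "progressor", "regressor"),
                       times = gn[c("stable", "progressor", "regressor")]),
                   levels = c("stable", "progressor", "regressor"))
  n_sub <- length(groups)
  ids <- gene_ids(config$n_genes)

  stage_num <- sample(1:4, n_sub, replace = TRUE,
                      prob = c(0.35, 0.30, 0.25, 0.10))
  nas <- pmin(8L, stage_num + rpois(n_sub, 2))
  subject_meta <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n_sub)),
    group = groups,
    fibrosis_stage = factor(paste0("F", stage_num),
                            levels = paste0("F", 1:4)),
    NAS = as.integer(nas), stringsAsFactors = FALSE)

  base <- rlnorm(config$n_genes, 0, 1)
  bg <- match(config$marker_sets$background, ids)
  base[bg] <- median(base) / 20
  rel <- matrix(base, config$n_genes, n_sub)
  for (nm in names(config$bulk_effect_log2fc)) {
    d <- config$bulk_effect_log2fc[[nm]]
    g <- match(config$marker_sets[[nm]], ids)
    rel[g, groups == "progressor"] <- rel[g, groups == "progressor"] * 2^d
    rel[g, groups == "regressor"] <- rel[g, groups == "regressor"] * 2^(-d)
  }
  # scale by the unmodified base total (not per-column sums) so that the
  # planted group contrasts stay exactly bulk_effect_log2fc on the log scale
  rel <- rel / sum(base)
  lib <- rlnorm(n_sub, config$bulk_libsize_log_mean, config$bulk_libsize_log_sd)
  mu <- sweep(rel, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), size = config$bulk_dispersion, mu = mu),
                   nrow = config$n_genes,
                   dimnames = list(ids, subject_meta$subject_id))
  out <- list(counts = counts, subject_meta = subject_meta)
  class(out) <- "bulk_cohort"
  out
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat("bulk_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "subjects\n")
  print(table(x$subject_meta$group))
  invisible(x)
}
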