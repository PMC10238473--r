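#' Run configuration for the power engine
#'
#' @param alpha two-sided significance level per test (default 0.025, i.e.
#'   0.05 split over two study endpoints; see \code{\link{alpha_adjust}}).
#' @param n_reps synthetic datasets per condition (100 for an initial scan,
#'   1000 for a final run).
#' @param methods subset of \code{c("wald_glmm", "lrt_glmm")} and/or names
#'   of entries in \code{plugins}.
#' @param seed master seed; per-condition, per-repeat seeds are derived by
#'   \code{\link{derive_seed}}, so grid cells are order-invariant.
#' @param target_power power goal used by \code{\link{required_n}}
#'   (default 0.8).
#' @param count_nonconverged count non-converged repeats as non-rejections
#'   instead of excluding them from the power denominator (default FALSE:
#'   power is rejections among converged repeats, with the convergence rate
#'   reported alongside).
#' @param plugins named list of additional test methods, each a
#'   \code{function(y, group, patient, offset)} returning a list with at
#'   least \code{p}, \code{lfc}, \code{converged}.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(alpha = 0.025, n_reps = 100L,
                       methods = "wald_glmm", seed = 1L,
                       target_power = 0.8, count_nonconverged = FALSE,
                       plugins = list()) {
  if (alpha <= 0 || alpha >= 1) stop_fmt("alpha must be in (0, 1)")
  if (n_reps < 1) stop_fmt("n_reps must be >= 1")
  known <- c("wald_glmm", "lrt_glmm", names(plugins))
  bad <- setdiff(methods, known)
  if (length(bad)) stop_fmt("unknown method(s): %s", paste(bad, collapse = ", "))
  structure(list(alpha = alpha, n_reps = as.integer(n_reps),
                 methods = methods, seed = as.integer(seed),
                 target_power = target_power,
                 count_nonconverged = count_nonconverged, plugins = plugins),
            class = "run_config")
}

# one repeat: assemble, normalize, test the endpoint gene with each method
run_one_rep <- function(cond, pool_control, pool_spiked, cfg, dropout = 0L) {
  ds <- assemble_dataset(cond, pool_control, pool_spiked)
  if (dropout > 0L) ds <- apply_dropout(ds, dropout)
  comp <- if ("composite" %in% names(ds$gene_meta)) ds$gene_meta$composite
          else rep(FALSE, nrow(ds$counts))
  els <- tmm_effective_libsize(ds$counts[!comp, , drop = FALSE])
  off <- log(els$effective)
  y <- as.numeric(ds$counts[cond$spike$gene, ])
  group <- factor(ds$roi_meta$group, levels = c("control", "spiked"))
  patient <- factor(ds$roi_meta$patient_id)
  out <- list()
  full_fit <- NULL
  for (m in cfg$methods) {
    res <- if (m == "wald_glmm") {
      if (is.null(full_fit)) full_fit <- fit_nb_glmm(y, group, patient, off)
      wald_test(full_fit)
    } else if (m == "lrt_glmm") {
      lrt_test(y, group, patient, off)
    } else {
      cfg$plugins[[m]](y, group, patient, off)
    }
    out[[m]] <- list(p = res$p, lfc = res$lfc,
                     converged = isTRUE(res$converged))
  }
  out
}

#' Estimate power for one design condition
#'
#' Runs \code{n_reps} independent synthetic datasets for the condition
#' (ROIs assembled from the pools, TMM effective library sizes, endpoint
#' gene tested by each method) and summarizes rejection rate and fold-change
#' distribution.  Each repeat uses a seed derived from the master seed, the
#' condition fields and the repeat index, so results do not depend on
#' execution order.
#'
#' @param cond a \code{\link{roi_condition}}.
#' @param pool_control,pool_spiked class-restricted spot pools (the spiked
#'   pool carries the condition's spike-in).
#' @param cfg a \code{\link{run_config}}.
#' @param dropout number of ROIs removed at random per dataset (default 0);
#'   see \code{\link{apply_dropout}}.
#' @return data.frame with one row per method: endpoint, method,
#'   n_patients, n_rois, diameter_um, spike_r, power, median_lfc, lfc_q1,
#'   lfc_q3, convergence_rate, n_reps, seed.  Power is the rejection
#'   fraction among converged repeats (all repeats when
#'   \code{cfg$count_nonconverged}); if nothing converged, power is NA.
#' @export
run_condition <- function(cond, pool_control, pool_spiked, cfg,
                          dropout = 0L) {
  stopifnot(inherits(cond, "roi_condition"), inherits(cfg, "run_config"))
  label <- condition_label(cond)
  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    set.seed(derive_seed(cfg$seed, label, dropout, r))
    reps[[r]] <- run_one_rep(cond, pool_control, pool_spiked, cfg, dropout)
  }
  rows <- lapply(cfg$methods, function(m) {
    p <- vapply(reps, function(x) x[[m]]$p, numeric(1))
    lfc <- vapply(reps, function(x) x[[m]]$lfc, numeric(1))
    conv <- vapply(reps, function(x) x[[m]]$converged, logical(1))
    use <- if (cfg$count_nonconverged) rep(TRUE, length(conv)) else conv
    rej <- !is.na(p) & p < cfg$alpha & conv
    power <- if (any(use)) sum(rej[use]) / sum(use) else NA_real_
    q <- if (any(conv)) quantile(lfc[conv], c(0.25, 0.5, 0.75), na.rm = TRUE)
         else rep(NA_real_, 3)
    data.frame(endpoint = cond$endpoint, method = m,
               n_patients = cond$n_patients_per_group,
               n_rois = cond$n_rois_per_patient,
               diameter_um = cond$roi_diameter_um,
               spike_r = cond$spike$r, power = power,
               median_lfc = q[2], lfc_q1 = q[1], lfc_q3 = q[3],
               convergence_rate = mean(conv), n_reps = cfg$n_reps,
               seed = cfg$seed, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run a grid of design conditions
#'
#' Applies \code{\link{run_condition}} to every condition; a failing cell is
#' reported as an NA row with a warning rather than aborting the grid.
#' Results are reproducible and order-invariant under a fixed master seed.
#'
#' @param conditions list of \code{\link{roi_condition}} objects.
#' @param pools named list with elements \code{control} and \code{spiked}
#'   per endpoint: \code{pools[[endpoint]]$control/$spiked}.
#' @param cfg a \code{\link{run_config}}.
#' @return long-format data.frame (one row per condition x method) suitable
#'   for power-surface plotting.
#' @export
run_grid <- function(conditions, pools, cfg) {
  rows <- lapply(conditions, function(cond) {
    pc <- pools[[cond$endpoint]]$control
    ps <- pools[[cond$endpoint]]$spiked
    tryCatch(run_condition(cond, pc, ps, cfg), error = function(e) {
      warn_fmt("condition %s failed: %s", condition_label(cond),
               conditionMessage(e))
      data.frame(endpoint = cond$endpoint, method = cfg$methods[1],
                 n_patients = cond$n_patients_per_group,
                 n_rois = cond$n_rois_per_patient,
                 diameter_um = cond$roi_diameter_um,
                 spike_r = cond$spike$r, power = NA_real_,
                 median_lfc = NA_real_, lfc_q1 = NA_real_, lfc_q3 = NA_real_,
                 convergence_rate = NA_real_, n_reps = cfg$n_reps,
                 seed = cfg$seed, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Smallest per-group sample size reaching a power target
#'
#' @param results data.frame with columns \code{n_patients} and \code{power}
#'   (one row per n, e.g. a filtered \code{\link{run_grid}} output).
#' @param target_power required power (default 0.8).
#' @return smallest n_patients with power >= target, or NA if never reached.
#' @export
required_n <- function(results, target_power = 0.8) {
  if (!nrow(results)) stop_fmt("required_n: empty results")
  o <- order(results$n_patients)
  n <- results$n_patients[o]; p <- results$power[o]
  hit <- which(!is.na(p) & p >= target_power)
  if (!length(hit)) return(NA_integer_)
  n[hit[1L]]
}

#' Power under ROI dropout
#'
#' Re-runs a condition with \code{n_remove} ROIs removed at random from each
#' assembled dataset (never fully depleting a patient), emulating technical
#' quality-control failures.  Repeat seeds are derived the same way as in
#' \code{\link{run_condition}}, so a run with \code{n_remove = 0} reproduces
#' the nominal result exactly.
#'
#' @param cond,pool_control,pool_spiked,cfg as in \code{\link{run_condition}}.
#' @param n_remove ROIs to remove per dataset.
#' @return data.frame as from \code{\link{run_condition}}, with an extra
#'   column \code{n_removed}.
#' @export
dropout_sensitivity <- function(cond, pool_control, pool_spiked, cfg,
                                n_remove) {
  out <- run_condition(cond, pool_control, pool_spiked, cfg,
                       dropout = n_remove)
  out$n_removed <- n_remove
  out
}

#' Total sample budget of a two-endpoint design
#'
#' \code{(n1 * r1 + n2 * r2) * n_groups}, doubled when an equal number of
#' paired follow-up samples is planned.
#'
#' @param n_patients_endpoint1,n_rois_1 design for the first endpoint.
#' @param n_patients_endpoint2,n_rois_2 design for the second endpoint
#'   (patients may be a subset of the first endpoint's).
#' @param n_groups number of experimental groups.
#' @param paired_followup double the total for follow-up sampling.
#' @return total number of samples.
#' @examples
#' sample_budget(10, 2, 5, 2, 3)        # 90
#' sample_budget(10, 2, 5, 2, 3, TRUE)  # 180
#' @export
sample_budget <- function(n_patients_endpoint1, n_rois_1,
                          n_patients_endpoint2, n_rois_2, n_groups,
                          paired_followup = FALSE) {
  stopifnot(n_patients_endpoint1 >= 0, n_rois_1 >= 0,
            n_patients_endpoint2 >= 0, n_rois_2 >= 0, n_groups >= 0)
  total <- (n_patients_endpoint1 * n_rois_1 +
              n_patients_endpoint2 * n_rois_2) * n_groups
  if (paired_followup) total <- 2 * total
  total
}

#' Split an alpha level over endpoints and genes
#'
#' \code{base_alpha / (n_endpoints * n_genes)}: 0.05 over two endpoints
#' gives the per-endpoint 0.025; additionally dividing by circa 2000
#' reliably detected genes gives the transcriptome-wide 1.25e-05.
#'
#' @param base_alpha family-wise level (default 0.05).
#' @param n_endpoints number of co-primary endpoints.
#' @param n_genes genes tested per endpoint (default 1).
#' @return the adjusted alpha.
#' @examples
#' alpha_adjust(0.05, 2)        # 0.025
#' alpha_adjust(0.05, 2, 2000)  # 1.25e-05
#' @export
alpha_adjust <- function(base_alpha = 0.05, n_endpoints, n_genes = 1) {
  stopifnot(base_alpha > 0, n_endpoints > 0, n_genes > 0)
  base_alpha / (n_endpoints * n_genes)
}

#' Plot a power surface
#'
#' Base-graphics matrix of power against patients per group, one line per
#' ROIs-per-patient value, faceted implicitly by line type.
#'
#' @param results \code{\link{run_grid}} output filtered to one endpoint,
#'   method and diameter.
#' @param target horizontal reference line (default 0.8).
#' @export
plot_power_surface <- function(results, target = 0.8) {
  rois <- sort(unique(results$n_rois))
  graphics::plot(range(results$n_patients), c(0, 1), type = "n",
                 xlab = "patients per group", ylab = "power")
  for (i in seq_along(rois)) {
    d <- results[results$n_rois == rois[i], ]
    d <- d[order(d$n_patients), ]
    graphics::lines(d$n_patients, d$power, type = "b", pch = i, lty = i)
  }
  graphics::abline(h = target, col = "grey50", lty = 3)
  graphics::legend("bottomright", legend = paste(rois, "ROIs/patient"),
                   pch = seq_along(rois), lty = seq_along(rois), bty = "n")
  invisible(results)
}
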