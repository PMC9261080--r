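#' Task connectome topology pipeline for a whole cohort
#'
#' Runs the full per-subject chain: concatenate the working-memory
#' (2-back) volumes, correlate, Fisher-z transform, residualize demographic
#' covariates across subjects, compute null-normalized metric curves over
#' the density grid, and synthesize each curve into one scalar per metric.
#'
#' @param cohort a \code{\link{generate_cohort}} table (or any data.frame
#'   with subject_id, group, age, sex, education).
#' @param ts_list named list of \code{\link{roi_timeseries}} (one per
#'   cohort row).
#' @param condition task condition to analyze (default "2back").
#' @param densities density grid (default \code{\link{default_densities}}).
#' @param k_null nulls per density (default 20).
#' @param seed integer seed for the null ensembles.
#' @param correct_covariates residualize age/sex/education (default TRUE).
#' @return data.frame with one row per subject: subject_id, group, and FDA
#'   scalars \code{C_fda}, \code{L_fda}, \code{gamma_fda},
#'   \code{lambda_fda}, \code{sigma_fda}; per-subject
#'   \code{\link{metric_curves}} objects in attribute \code{"curves"}.
#' @export
cohort_topology <- function(cohort, ts_list, condition = "2back",
                            densities = default_densities(), k_null = 20,
                            seed = 1L, correct_covariates = TRUE) {
  stopifnot(nrow(cohort) == length(ts_list))
  mats <- lapply(ts_list, function(ts)
    fisher_z(correlation_matrix(extract_condition_volumes(ts, condition))))
  if (correct_covariates)
    mats <- regress_covariates(mats, cohort)
  curves <- lapply(seq_along(mats), function(i)
    metric_curves(mats[[i]], densities = densities, k_null = k_null,
                  seed = seed + 1000L * i))
  names(curves) <- cohort$subject_id
  out <- data.frame(
    subject_id = cohort$subject_id,
    group = cohort$group,
    C_fda = vapply(curves, fda_synthesize, numeric(1), metric = "C"),
    L_fda = vapply(curves, fda_synthesize, numeric(1), metric = "L"),
    gamma_fda = vapply(curves, fda_synthesize, numeric(1), metric = "gamma"),
    lambda_fda = vapply(curves, fda_synthesize, numeric(1), metric = "lambda"),
    sigma_fda = vapply(curves, fda_synthesize, numeric(1), metric = "sigma"),
    row.names = NULL)
  attr(out, "curves") <- curves
  out
}

#' Regional clustering group statistics with FDR correction
#'
#' For every node, synthesizes the per-node clustering curve across
#' densities (same functional synthesis as the global metrics), runs a
#' one-way group ANOVA, and corrects the per-node p-values with the
#' Benjamini-Hochberg procedure.
#'
#' @param curves list of \code{\link{metric_curves}} (one per subject).
#' @param groups per-subject group labels.
#' @param q FDR level (default 0.05).
#' @return data.frame: node_id, F, p_raw, p_fdr, reject.
#' @export
regional_group_stats <- function(curves, groups, q = 0.05) {
  reg <- vapply(curves, function(cu) rowSums(cu$regional),
                numeric(nrow(curves[[1]]$regional)))  # nodes x subjects
  res <- apply(reg, 1, function(v) {
    a <- anova_oneway(v, groups)
    c(a$statistic, a$p)
  })
  fdr <- bh_fdr(res[2, ], q = q)
  node_id <- rownames(curves[[1]]$regional)
  if (is.null(node_id)) node_id <- paste0("N", seq_len(ncol(res)))
  data.frame(node_id = node_id, F = res[1, ], p_raw = res[2, ],
             p_fdr = fdr$adjusted, reject = fdr$reject, row.names = NULL)
}
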