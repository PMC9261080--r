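#' Collapse a metric-versus-density curve to one scalar
#'
#' Functional synthesis of a network-metric curve: the metric's values are
#' summed across all densities of the grid, giving the single number per
#' subject that enters group ANOVA. The sum is linear in the curve and, on a
#' uniform grid, proportional to the Riemann area under it, so any affine
#' reading of the synthesis preserves group ordering.
#'
#' @param curve a \code{\link{metric_curves}} object.
#' @param metric one of \code{"C"}, \code{"L"}, \code{"gamma"},
#'   \code{"lambda"}, \code{"sigma"}.
#' @return scalar sum across densities.
#' @export
fda_synthesize <- function(curve, metric = c("sigma", "gamma", "lambda", "C", "L")) {
  stopifnot(inherits(curve, "metric_curve"))
  metric <- match.arg(metric)
  y <- curve$curve[[metric]]
  if (anyNA(y)) stop("curve has missing density points for metric ", metric,
                     call. = FALSE)
  sum(y)
}

new_stat_test <- function(statistic, df, p, kind, posthoc = NULL) {
  structure(list(statistic = statistic, df = df, p = p, test_kind = kind,
                 posthoc = posthoc),
            class = "stat_test")
}

#' One-way ANOVA from raw values
#'
#' Classical fixed-effects one-way analysis of variance:
#' \code{F = MS_between / MS_within} on \code{(g - 1, N - g)} degrees of
#' freedom.
#'
#' @param values numeric vector of per-subject scalars.
#' @param groups group labels, same length.
#' @return object of class \code{"stat_test"} with fields \code{statistic}
#'   (F), \code{df}, \code{p}, \code{test_kind}.
#' @export
anova_oneway <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs n >= 2; too small: ",
                         paste(names(tab)[tab < 2], collapse = ", "),
                         call. = FALSE)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  new_stat_test(statistic = s[["F value"]][1],
                df = c(s[["Df"]][1], s[["Df"]][2]),
                p = s[["Pr(>F)"]][1], kind = "anova")
}

#' One-way ANOVA reconstructed from printed summaries
#'
#' Recovers the omnibus F statistic from per-group (mean, dispersion, n) as
#' printed in a results table. The dispersion kind must be declared
#' explicitly: published tables sometimes label standard errors as SDs, and
#' a silent assumption would corrupt the reconstruction. With
#' \code{dispersion_kind = "sem"}, \code{SD = dispersion * sqrt(n)} per
#' group. Then \code{SS_between} is taken about the size-weighted grand
#' mean and \code{SS_within = sum((n_g - 1) SD_g^2)}.
#'
#' @param means per-group means.
#' @param dispersions per-group dispersions (SD or SEM).
#' @param n per-group sizes.
#' @param dispersion_kind \code{"sd"} or \code{"sem"}; no default.
#' @return a \code{"stat_test"} with the F statistic, df and p.
#' @export
anova_from_summary <- function(means, dispersions, n, dispersion_kind) {
  if (missing(dispersion_kind))
    stop("dispersion_kind must be given explicitly ('sd' or 'sem')",
         call. = FALSE)
  dispersion_kind <- match.arg(dispersion_kind, c("sd", "sem"))
  stopifnot(length(means) == length(dispersions),
            length(means) == length(n))
  if (length(means) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(dispersions < 0)) stop("dispersions must be >= 0", call. = FALSE)
  sds <- if (dispersion_kind == "sem") dispersions * sqrt(n) else dispersions
  N <- sum(n); g <- length(n)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum((n - 1) * sds^2)
  Fstat <- (ss_between / (g - 1)) / (ss_within / (N - g))
  new_stat_test(statistic = Fstat, df = c(g - 1, N - g),
                p = stats::pf(Fstat, g - 1, N - g, lower.tail = FALSE),
                kind = "anova_summary")
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction, df = (r - 1)(c - 1).
#'
#' @param counts matrix of nonnegative integer counts.
#' @return a \code{"stat_test"} with the chi-square statistic, df and p.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_stat_test(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value, kind = "chi_square")
}

#' Post hoc pairwise comparisons after a one-way ANOVA
#'
#' All pairwise group comparisons by Tukey's HSD (default), unadjusted
#' pairwise t tests, or Bonferroni-adjusted t tests.
#'
#' @param values numeric per-subject scalars.
#' @param groups group labels.
#' @param method \code{"tukey_hsd"}, \code{"t_unadjusted"}, or
#'   \code{"t_bonferroni"}.
#' @return a \code{"stat_test"} whose \code{posthoc} field is a data.frame
#'   (comparison, estimate, p).
#' @export
posthoc_pairwise <- function(values, groups,
                             method = c("tukey_hsd", "t_unadjusted",
                                        "t_bonferroni")) {
  method <- match.arg(method)
  omnibus <- anova_oneway(values, groups)
  groups <- droplevels(factor(groups[is.finite(values)]))
  values <- values[is.finite(values)]
  if (method == "tukey_hsd") {
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    ph <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                     p = tk[, "p adj"], row.names = NULL)
  } else {
    adj <- if (method == "t_bonferroni") "bonferroni" else "none"
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = adj,
                                 pool.sd = TRUE)
    pm <- pt$p.value
    comparisons <- character(0); ps <- numeric(0); est <- numeric(0)
    gm <- tapply(values, groups, mean)
    for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm)))
      if (!is.na(pm[i, j])) {
        comparisons <- c(comparisons,
                         paste(rownames(pm)[i], colnames(pm)[j], sep = "-"))
        est <- c(est, gm[[rownames(pm)[i]]] - gm[[colnames(pm)[j]]])
        ps <- c(ps, pm[i, j])
      }
    ph <- data.frame(comparison = comparisons, estimate = est, p = ps)
  }
  omnibus$posthoc <- ph
  omnibus$test_kind <- paste0("anova+", method)
  omnibus
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: adjusted \code{p_(i) = min_{j >= i} (m/j) p_(j)},
#' capped at 1; hypotheses with adjusted p <= q are rejected.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (BH-adjusted p-values, input order) and
#'   \code{reject} (logical flags).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' @export
print.stat_test <- function(x, ...) {
  lab <- if (grepl("chi", x$test_kind)) "X-squared" else "F"
  cat(sprintf("%s test: %s = %.4f, df = %s, p = %.4g\n", x$test_kind, lab,
              x$statistic, paste(x$df, collapse = ", "), x$p))
  if (!is.null(x$posthoc)) {
    cat("Post hoc comparisons:\n")
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
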