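#' Genotype matrix container
#'
#' Subjects x SNPs dosage matrix (counts of the effect allele, 0/1/2, NA for
#' missing calls) with per-SNP metadata.
#'
#' @param subjects ordered subject ids.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based), \code{effect_allele}, \code{other_allele}.
#' @param dosages subjects x SNPs matrix with entries in \{0, 1, 2, NA\}.
#' @return object of class \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(subjects, snps, dosages) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!is.data.frame(snps) || !all(req %in% names(snps)))
    stop("snps must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(subjects) || ncol(dosages) != nrow(snps))
    stop("dosages must be subjects x SNPs", call. = FALSE)
  vals <- dosages[!is.na(dosages)]
  if (any(!vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (any(snps$pos < 0)) stop("positions must be nonnegative", call. = FALSE)
  dimnames(dosages) <- list(subjects, snps$snp_id)
  structure(list(subjects = subjects, snps = snps, dosages = dosages),
            class = "genotype_matrix")
}

snp_stats <- function(g) {
  d <- g$dosages
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2            # effect-allele frequency
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[!is.na(d[, j]), j]
    m <- length(x)
    if (m == 0) return(NA_real_)
    f <- mean(x) / 2
    if (f == 0 || f == 1) return(1)              # monomorphic: nothing to test
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    exp <- m * c((1 - f)^2, 2 * f * (1 - f), f^2)
    stat <- sum((obs - exp)^2 / exp)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  data.frame(snp_id = g$snps$snp_id, call_rate = call_rate, af = af,
             maf = maf, hwe_p = hwe_p, row.names = NULL)
}

#' Genotype quality control
#'
#' Removes SNPs with call rate below \code{call_rate_min}, minor allele
#' frequency below \code{maf_min}, or a Hardy-Weinberg equilibrium
#' goodness-of-fit chi-square (1 df, genotype counts against the HWE
#' expectation in the full sample) p-value below \code{hwe_p_min}. Per-filter
#' removal counts are attached as the \code{"qc_log"} attribute.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param call_rate_min minimum call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return filtered \code{genotype_matrix}.
#' @export
qc_filter <- function(g, call_rate_min = 0.95, maf_min = 0.01,
                      hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosages) == 0) stop("empty genotype matrix", call. = FALSE)
  st <- snp_stats(g)
  fail_call <- st$call_rate < call_rate_min
  fail_maf <- st$maf < maf_min
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < hwe_p_min
  drop <- fail_call | fail_maf | fail_hwe
  log <- c(call_rate = sum(fail_call), maf = sum(fail_maf),
           hwe = sum(fail_hwe), total_removed = sum(drop),
           retained = sum(!drop))
  if (all(drop))
    stop("all SNPs removed by QC (call_rate: ", log["call_rate"],
         ", maf: ", log["maf"], ", hwe: ", log["hwe"], ")", call. = FALSE)
  out <- genotype_matrix(g$subjects, g$snps[!drop, , drop = FALSE],
                         g$dosages[, !drop, drop = FALSE])
  attr(out, "qc_log") <- log
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two SNPs' dosage vectors over subjects
#' with both calls present.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param i,j SNP ids or column indices.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  xi <- g$dosages[, i]; xj <- g$dosages[, j]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  if (stats::var(xi[ok]) == 0 || stats::var(xj[ok]) == 0)
    stop("zero dosage variance at SNP ", if (stats::var(xi[ok]) == 0) i else j,
         call. = FALSE)
  stats::cor(xi[ok], xj[ok])^2
}

#' Greedy LD clumping of GWAS-weighted SNPs
#'
#' Visits SNPs shared between the genotype matrix and the weights table in
#' order of ascending GWAS p-value (ties broken by lower chromosome, then
#' position) and retains a SNP only if no already-retained SNP on the same
#' chromosome within \code{window_kb} kilobases has dosage r-squared >=
#' \code{r2_max} with it.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param w weights data.frame (\code{snp_id}, \code{effect_allele},
#'   \code{OR}, \code{p}).
#' @param r2_max LD threshold (default 0.2).
#' @param window_kb physical window in kb (default 500).
#' @return character vector of retained (index) SNP ids.
#' @export
clump <- function(g, w, r2_max = 0.2, window_kb = 500) {
  stopifnot(inherits(g, "genotype_matrix"))
  shared <- intersect(g$snps$snp_id, w$snp_id)
  if (length(shared) == 0)
    stop("no overlapping SNPs between genotypes and weights", call. = FALSE)
  meta <- g$snps[match(shared, g$snps$snp_id), ]
  p <- w$p[match(shared, w$snp_id)]
  ord <- order(p, meta$chrom, meta$pos)
  kept <- character(0)
  kept_meta <- meta[0, ]
  window <- window_kb * 1000
  for (k in ord) {
    cand <- meta[k, ]
    near <- which(kept_meta$chrom == cand$chrom &
                    abs(kept_meta$pos - cand$pos) <= window)
    blocked <- FALSE
    for (m in near) {
      r2 <- tryCatch(ld_r2(g, cand$snp_id, kept_meta$snp_id[m]),
                     error = function(e) 0)
      if (r2 >= r2_max) { blocked <- TRUE; break }
    }
    if (!blocked) {
      kept <- c(kept, cand$snp_id)
      kept_meta <- rbind(kept_meta, cand)
    }
  }
  kept[order(match(kept, g$snps$snp_id))]
}

# orient dosages to the weights' effect allele; NA rows in `beta` mark drops
orient_dosages <- function(g, w) {
  idx <- match(w$snp_id, g$snps$snp_id)
  keep <- !is.na(idx)
  w <- w[keep, , drop = FALSE]; idx <- idx[keep]
  d <- g$dosages[, idx, drop = FALSE]
  geno_ea <- g$snps$effect_allele[idx]
  geno_oa <- g$snps$other_allele[idx]
  same <- w$effect_allele == geno_ea
  flipped <- w$effect_allele == geno_oa
  bad <- !same & !flipped
  d[, flipped] <- 2 - d[, flipped, drop = FALSE]
  list(dosages = d[, !bad, drop = FALSE], w = w[!bad, , drop = FALSE],
       n_dropped = sum(bad))
}

#' Polygenic risk score at one p-value threshold
#'
#' Weighted allele count: for each subject, the sum over scoring SNPs
#' (those surviving clumping, with GWAS p <= threshold) of
#' \code{log(OR) * dosage}. Dosages are oriented to the weights' effect
#' allele (reversed as \code{2 - d} when the genotype file labels the other
#' allele as effect); SNPs matching neither allele are dropped with the
#' count in attribute \code{"n_allele_dropped"}. Missing dosages are imputed
#' as twice the effect-allele frequency.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param w weights data.frame (\code{snp_id}, \code{effect_allele},
#'   \code{OR}, \code{p}).
#' @param p_threshold GWAS p-value cutoff.
#' @param snp_set optional vector of clumped SNP ids to score within
#'   (default: all shared SNPs).
#' @return named per-subject score vector.
#' @export
prs_score <- function(g, w, p_threshold = 1, snp_set = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(snp_set)) w <- w[w$snp_id %in% snp_set, , drop = FALSE]
  w <- w[w$p <= p_threshold, , drop = FALSE]
  ori <- orient_dosages(g, w)
  if (ncol(ori$dosages) == 0)
    stop("no scorable SNPs at threshold ", p_threshold,
         " (allele-mismatch drops: ", ori$n_dropped, ")", call. = FALSE)
  d <- ori$dosages
  af <- colMeans(d, na.rm = TRUE) / 2
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- 2 * af[j]
  }
  scores <- as.numeric(d %*% log(ori$w$OR))
  names(scores) <- g$subjects
  attr(scores, "n_snps") <- ncol(d)
  attr(scores, "n_allele_dropped") <- ori$n_dropped
  scores
}

#' Default p-value threshold grid for multi-threshold scoring
#'
#' Landmark thresholds 5e-8, 5e-5, 5e-3 plus a dense grid from 0.1 to 1 in
#' steps of 1e-4 (with 0.5 and 1 included), a dense-grid-plus-landmarks
#' design of several thousand scores.
#' @return increasing numeric vector of thresholds.
#' @export
prs_default_thresholds <- function()
  sort(unique(c(5e-8, 5e-5, 5e-3, seq(0.1, 1, by = 1e-4), 0.5, 1)))

#' Polygenic scores across a grid of p-value thresholds
#'
#' Scores every subject at each threshold of the grid over the clumped SNP
#' set, reusing a single pass over the SNPs sorted by GWAS p (the score at a
#' threshold is the cumulative sum of per-SNP contributions up to it).
#'
#' @param g a \code{\link{genotype_matrix}} (ideally after
#'   \code{\link{qc_filter}}).
#' @param w weights data.frame.
#' @param thresholds increasing p-value cutoffs
#'   (default \code{\link{prs_default_thresholds}()}).
#' @param clump_r2,window_kb clumping parameters (see \code{\link{clump}});
#'   set \code{clump_r2 = NULL} to skip clumping.
#' @return subjects x thresholds score matrix; attribute \code{"n_snps"}
#'   gives the number of scoring SNPs per threshold.
#' @export
prs_profile <- function(g, w, thresholds = prs_default_thresholds(),
                        clump_r2 = 0.2, window_kb = 500) {
  snp_set <- if (is.null(clump_r2)) NULL else
    clump(g, w, r2_max = clump_r2, window_kb = window_kb)
  ww <- if (is.null(snp_set)) w else w[w$snp_id %in% snp_set, , drop = FALSE]
  ori <- orient_dosages(g, ww)
  if (ncol(ori$dosages) == 0) stop("no scorable SNPs", call. = FALSE)
  d <- ori$dosages
  af <- colMeans(d, na.rm = TRUE) / 2
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- 2 * af[j]
  }
  contrib <- sweep(d, 2, log(ori$w$OR), `*`)
  ord <- order(ori$w$p)
  cum <- cbind(0, t(apply(contrib[, ord, drop = FALSE], 1, cumsum)))
  n_in <- findInterval(thresholds, sort(ori$w$p))
  scores <- cum[, n_in + 1, drop = FALSE]
  dimnames(scores) <- list(g$subjects, format(thresholds, trim = TRUE))
  attr(scores, "n_snps") <- stats::setNames(n_in, colnames(scores))
  attr(scores, "n_allele_dropped") <- ori$n_dropped
  scores
}

#' Synthesize multi-threshold scores into one polygenic profile
#'
#' Standardizes the per-threshold score columns (constant columns are
#' dropped with a warning) and extracts the first principal component; the
#' per-subject projection on it is the synthesized score. The component sign
#' is fixed so the synthesized score correlates positively with the mean
#' standardized score.
#'
#' @param scores subjects x thresholds matrix (from \code{\link{prs_profile}}).
#' @return object of class \code{"prs_profile"}: list with
#'   \code{thresholds}, \code{scores}, \code{synthesized} (per-subject first
#'   PC score), \code{explained_variance}.
#' @export
synthesize_prs <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need >= 2 thresholds", call. = FALSE)
  if (nrow(scores) < 3) stop("need >= 3 subjects", call. = FALSE)
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant score column(s) dropped before PCA",
            call. = FALSE)
    scores_use <- scores[, sds > 0, drop = FALSE]
    if (ncol(scores_use) < 2)
      stop("fewer than 2 non-constant score columns", call. = FALSE)
  } else scores_use <- scores
  pc <- stats::prcomp(scores_use, center = TRUE, scale. = TRUE)
  synth <- pc$x[, 1]
  ev <- pc$sdev[1]^2 / sum(pc$sdev^2)
  ref <- rowMeans(scale(scores_use))
  if (stats::sd(ref) > 0 && stats::cor(synth, ref) < 0) synth <- -synth
  structure(list(thresholds = colnames(scores), scores = scores,
                 synthesized = stats::setNames(as.numeric(synth),
                                               rownames(scores)),
                 explained_variance = ev),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf(paste0("PRS profile: %d subjects x %d thresholds; first PC ",
                     "explains %.1f%% of variance\n"),
              nrow(x$scores), ncol(x$scores), 100 * x$explained_variance))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}
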