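toy_geno <- function(dosages, chrom = NULL, pos = NULL) {
  ns <- ncol(dosages)
  snps <- data.frame(snp_id = paste0("s", seq_len(ns)),
                     chrom = if (is.null(chrom)) rep(1, ns) else chrom,
                     pos = if (is.null(pos)) seq_len(ns) * 1000 else pos,
                     effect_allele = "A", other_allele = "G")
  genotype_matrix(paste0("I", seq_len(nrow(dosages))), snps, dosages)
}

test_that("QC removes low-call-rate, rare, and HWE-violating SNPs", {
  set.seed(2)
  n <- 200
  good <- replicate(3, rbinom(n, 2, 0.3))
  low_call <- rbinom(n, 2, 0.3); low_call[1:90] <- NA        # 45% missing
  mono <- rep(0L, n)                                          # MAF 0
  hwe_bad <- rep(c(0L, 2L), n / 2)                            # no heterozygotes
  g <- toy_geno(cbind(good, low_call, mono, hwe_bad))
  out <- qc_filter(g)
  expect_identical(out$snps$snp_id, paste0("s", 1:3))
  log <- attr(out, "qc_log")
  expect_gte(log[["call_rate"]], 1)
  expect_gte(log[["maf"]], 1)
  expect_gte(log[["hwe"]], 1)
  # idempotence
  out2 <- qc_filter(out)
  expect_identical(out2$dosages, out$dosages)
  expect_error(qc_filter(toy_geno(cbind(mono, mono))), "all SNPs removed")
})

test_that("HWE chi-square matches the hand computation for (100, 0, 100)", {
  d <- matrix(rep(c(0L, 2L), 100), ncol = 1)
  st <- wmtopo:::snp_stats(toy_geno(cbind(d, rbinom(200, 2, 0.4))))
  # f = 0.5: expected (50, 100, 50); chi2 = 50 + 100 + 50 = 200
  expect_equal(st$hwe_p[1], pchisq(200, 1, lower.tail = FALSE))
  expect_lt(st$hwe_p[1], 1e-6)
})

test_that("LD r-squared is the squared dosage correlation", {
  set.seed(4)
  x <- rbinom(500, 2, 0.4)
  g <- toy_geno(cbind(x, x, rbinom(500, 2, 0.4)))
  expect_equal(ld_r2(g, 1, 2), 1)
  expect_lt(ld_r2(g, 1, 3), 0.03)
  g0 <- toy_geno(cbind(x, rep(1L, 500)))
  expect_error(ld_r2(g0, 1, 2), "variance")
})

test_that("clumping keeps index SNPs and respects the physical window", {
  set.seed(6)
  x <- rbinom(300, 2, 0.4)
  y <- rbinom(300, 2, 0.4)
  # s1/s2 perfectly correlated 1 kb apart; s3 independent
  g <- toy_geno(cbind(x, x, y), pos = c(1000, 2000, 900000))
  w <- data.frame(snp_id = c("s1", "s2", "s3"), effect_allele = "A",
                  OR = c(1.2, 1.1, 1.3), p = c(1e-8, 1e-4, 0.2))
  expect_identical(clump(g, w), c("s1", "s3"))
  # same correlated pair 600 kb apart: both survive
  g2 <- toy_geno(cbind(x, x), pos = c(1000, 601000))
  w2 <- w[1:2, ]
  expect_identical(clump(g2, w2), c("s1", "s2"))
  expect_error(clump(g, data.frame(snp_id = "zz", effect_allele = "A",
                                   OR = 1, p = 0.5)), "overlap")
})

test_that("clumping matches the definition oracle on correlated blocks", {
  for (s in 1:8) {
    set.seed(s)
    n <- 400
    u <- rnorm(n)
    d <- sapply(1:5, function(j) {
      x <- sqrt(0.6) * u + sqrt(0.4) * rnorm(n)
      f <- runif(1, 0.2, 0.5)
      as.integer((x > qnorm((1 - f)^2)) + (x > qnorm(1 - f^2)))
    })
    pos <- sort(sample.int(400000, 5))
    g <- toy_geno(d, pos = pos)
    p <- runif(5)
    w <- data.frame(snp_id = paste0("s", 1:5), effect_allele = "A",
                    OR = exp(rnorm(5, 0, 0.1)), p = p)
    expect_identical(sort(clump(g, w)),
                     oracle_clump(d, g$snps, p))
  }
})

test_that("single-SNP scores follow log(OR) times dosage", {
  g <- toy_geno(matrix(c(0L, 1L, 2L), ncol = 1))
  w <- data.frame(snp_id = "s1", effect_allele = "A", OR = 2, p = 1e-4)
  expect_equal(as.numeric(prs_score(g, w)), c(0, log(2), 2 * log(2)))
  # allele relabeling with reversed dosages leaves scores unchanged
  g_flip <- toy_geno(matrix(c(2L, 1L, 0L), ncol = 1))
  g_flip$snps$effect_allele <- "G"; g_flip$snps$other_allele <- "A"
  expect_equal(as.numeric(prs_score(g_flip, w)),
               as.numeric(prs_score(g, w)))
  # unresolvable mismatch drops the SNP; all dropped is an error
  g_bad <- g; g_bad$snps$effect_allele <- "C"; g_bad$snps$other_allele <- "T"
  expect_error(prs_score(g_bad, w), "no scorable")
})

test_that("threshold profiles use exactly the SNPs at or below each cutoff", {
  set.seed(11)
  d <- matrix(rbinom(50 * 6, 2, 0.4), 50, 6)
  g <- toy_geno(d, pos = seq(1e6, 6e6, by = 1e6))  # far apart: no clumping
  w <- data.frame(snp_id = paste0("s", 1:6), effect_allele = "A",
                  OR = exp(c(0.3, -0.2, 0.1, 0.25, -0.15, 0.05)),
                  p = c(1e-8, 1e-5, 1e-3, 0.04, 0.3, 0.9))
  thr <- c(1e-6, 1e-4, 0.05, 1)
  prof <- prs_profile(g, w, thresholds = thr, clump_r2 = NULL)
  for (k in seq_along(thr)) {
    direct <- as.numeric(d[, w$p <= thr[k], drop = FALSE] %*%
                           log(w$OR[w$p <= thr[k]]))
    expect_equal(unname(prof[, k]), direct, tolerance = 1e-12)
  }
  # invariance to SNP column order and subject row order
  perm <- c(4, 2, 6, 1, 3, 5); rperm <- sample(50)
  g2 <- toy_geno(d[rperm, perm], pos = seq(1e6, 6e6, by = 1e6)[perm])
  g2$snps$snp_id <- paste0("s", 1:6)[perm]
  g2 <- genotype_matrix(paste0("I", seq_len(50))[rperm], g2$snps, g2$dosages)
  prof2 <- prs_profile(g2, w, thresholds = thr, clump_r2 = NULL)
  expect_equal(prof2[rownames(prof), ], prof[, ], tolerance = 1e-12)
})

test_that("missing dosages are imputed at twice the allele frequency", {
  d <- matrix(c(NA, 1L, 2L, 0L), ncol = 1)
  g <- toy_geno(d)
  w <- data.frame(snp_id = "s1", effect_allele = "A", OR = exp(1), p = 0.01)
  sc <- prs_score(g, w)
  expect_equal(unname(sc[1]), 2 * mean(c(1, 2, 0)) / 2)
})

test_that("first-PC synthesis captures a one-factor score matrix", {
  set.seed(13)
  f <- rnorm(100)
  scores <- sapply(1:8, function(k) 2 * f + rnorm(100, 0, 0.3))
  syn <- synthesize_prs(scores)
  expect_gt(syn$explained_variance, 0.9)
  expect_gt(cor(syn$synthesized, f)^2, 0.9)
  # sign convention: positive correlation with the mean standardized score
  expect_gte(cor(syn$synthesized, rowMeans(scale(scores))), 0)
  # two identical columns are rank one
  two <- cbind(f, f)
  expect_equal(synthesize_prs(two)$explained_variance, 1)
  # constant columns dropped with a warning
  expect_warning(syn3 <- synthesize_prs(cbind(f, f + rnorm(100, 0, 0.1),
                                              rep(2, 100))), "constant")
  expect_length(syn3$synthesized, 100)
})
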