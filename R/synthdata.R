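#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator with validated
#' defaults. The defaults emulate a three-group early-onset schizophrenia
#' study: 27 cases (EOS), 24 unaffected siblings (SB), 48 healthy controls
#' (HC); a block-design n-back task (4 blocks per load condition); a
#' 264-node parcellation; and an EOS-specific elevation of network
#' clustering during the working-memory (2-back) condition.
#'
#' @param group_sizes named integer vector, subjects per group
#'   (default \code{c(EOS = 27, SB = 24, HC = 48)}).
#' @param n_nodes number of ROIs (default 264; desk-scale analyses typically
#'   use 60-90).
#' @param n_volumes_per_block fMRI volumes per task block (default 30).
#' @param n_blocks blocks per load condition (default 4).
#' @param effect_scale multiplier on every between-group mean difference in
#'   demographics and behavior; 0 gives the null configuration (default 1).
#' @param clustering_effect named per-group relative elevation of 2-back
#'   network clustering (default \code{c(EOS = 0.5, SB = 0, HC = 0)}); it
#'   simultaneously raises the group's connectome coupling and makes its
#'   ground-truth network more lattice-like.
#' @param base_coupling baseline connectome coupling strength in (0, 1)
#'   controlling the signal-to-noise of the task covariance (default 0.55).
#' @param coupling_sd relative subject-level SD of the coupling (default 0.08).
#' @param latent_corr named vector of latent correlations linking genetic
#'   liability ("liab"), negative/positive symptoms ("neg"/"pos"), network
#'   topology ("topo") and 2-back accuracy ("acc"); names are pairs like
#'   \code{"neg_topo"}. Unlisted pairs are 0.
#' @param ws_neighbors lattice neighborhood of the ground-truth small-world
#'   network (each node links to \code{ws_neighbors} neighbors per side;
#'   default 6).
#' @param ws_rewire_2back ground-truth rewiring probability of the 2-back
#'   network for a group with zero clustering effect (default 0.15).
#' @param ws_rewire_0back rewiring probability of the (shared, less
#'   clustered) 0-back network (default 0.9).
#' @param weight_range range of ground-truth edge weights (default
#'   \code{c(0.5, 1)}).
#' @param n_causal number of causal SNPs carrying nonzero GWAS weights
#'   (default 50).
#' @param ld_block_size SNPs per LD block (default 10).
#' @param ld_latent_corr latent within-block correlation generating LD
#'   (dosage r-squared is somewhat lower; default 0.7).
#' @param genetic_coupling loading of the cohort's latent liability on
#'   causal-SNP dosages (default 0.2).
#' @param missing_rate genotype missingness rate (default 0.01).
#' @param symptoms_all_groups record symptom scores for every group rather
#'   than cases only (default FALSE).
#' @param seed integer master seed recorded in every output (default 1).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(group_sizes = c(EOS = 27, SB = 24, HC = 48),
                       n_nodes = 264,
                       n_volumes_per_block = 30,
                       n_blocks = 4,
                       effect_scale = 1,
                       clustering_effect = c(EOS = 0.5, SB = 0, HC = 0),
                       base_coupling = 0.55,
                       coupling_sd = 0.08,
                       latent_corr = c(liab_neg = 0.3, liab_topo = 0.5,
                                       liab_acc = -0.2, neg_pos = 0.4,
                                       neg_topo = 0.4, neg_acc = -0.3,
                                       topo_acc = 0.2),
                       ws_neighbors = 6,
                       ws_rewire_2back = 0.15,
                       ws_rewire_0back = 0.9,
                       weight_range = c(0.5, 1),
                       n_causal = 50,
                       ld_block_size = 10,
                       ld_latent_corr = 0.7,
                       genetic_coupling = 0.2,
                       missing_rate = 0.01,
                       symptoms_all_groups = FALSE,
                       seed = 1L) {
  if (length(group_sizes) < 2 || any(group_sizes <= 0))
    stop("group_sizes must be >= 2 groups, each of positive size", call. = FALSE)
  if (is.null(names(group_sizes))) names(group_sizes) <- c("EOS", "SB", "HC")[seq_along(group_sizes)]
  if (n_nodes <= 2 * ws_neighbors)
    stop("n_nodes must exceed twice ws_neighbors (the lattice neighborhood)",
         call. = FALSE)
  stopifnot(n_nodes >= 3, n_volumes_per_block >= 2, n_blocks >= 1,
            is.finite(effect_scale), base_coupling > 0, base_coupling < 1,
            ws_neighbors >= 1, n_causal >= 0, ld_block_size >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!all(is.finite(clustering_effect)))
    stop("clustering_effect values must be finite", call. = FALSE)
  ce <- rep(0, length(group_sizes)); names(ce) <- names(group_sizes)
  ce[intersect(names(clustering_effect), names(ce))] <-
    clustering_effect[intersect(names(clustering_effect), names(ce))]
  R <- latent_corr_matrix(latent_corr)
  cfg <- list(group_sizes = group_sizes, n_nodes = n_nodes,
              n_volumes_per_block = n_volumes_per_block, n_blocks = n_blocks,
              effect_scale = effect_scale, clustering_effect = ce,
              base_coupling = base_coupling, coupling_sd = coupling_sd,
              latent_corr = latent_corr, latent_R = R,
              ws_neighbors = ws_neighbors,
              ws_rewire_2back = ws_rewire_2back,
              ws_rewire_0back = ws_rewire_0back,
              weight_range = weight_range, n_causal = n_causal,
              ld_block_size = ld_block_size,
              ld_latent_corr = ld_latent_corr,
              genetic_coupling = genetic_coupling,
              missing_rate = missing_rate,
              symptoms_all_groups = symptoms_all_groups,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

latent_corr_matrix <- function(latent_corr) {
  v <- c("liab", "neg", "pos", "topo", "acc")
  R <- diag(5); dimnames(R) <- list(v, v)
  for (nm in names(latent_corr)) {
    pair <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% v))
      stop("unknown latent_corr name: ", nm, call. = FALSE)
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- latent_corr[[nm]]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("latent correlation matrix is not positive definite", call. = FALSE)
  R
}

# reference per-group summaries the demographic generator is aimed at
# (three-group working-memory cohort: cases / siblings / controls)
group_profiles <- function() {
  list(age  = list(m = c(18.37, 19.92, 19.73), s = c(3.3, 3.3, 3.3)),
       edu  = list(m = c(10.63, 11.50, 12.50), s = c(2.6, 2.5, 2.6)),
       male = list(m = c(14 / 27, 8 / 24, 28 / 48)),
       acc2 = list(m = c(0.70, 0.77, 0.84), s = c(0.14, 0.18, 0.12)),
       acc0 = list(m = c(0.88, 0.87, 0.94), s = c(0.16, 0.20, 0.09)),
       fd   = list(m = c(7.88, 8.33, 9.28), s = c(11.09, 11.48, 13.9)),
       neg  = list(m = 17.89, s = 9.2),
       pos  = list(m = 13.67, s = 7.4))
}

#' Generate a synthetic cohort table
#'
#' Draws one subject row per configured slot: group, demographics (age, sex,
#' education), symptom scores (cases only unless
#' \code{symptoms_all_groups}), 0-back/2-back task accuracies, and the count
#' of motion-interpolated fMRI volumes. Subjects also carry two simulation
#' ground-truth columns: \code{liability_truth} (latent genetic liability)
#' and \code{coupling_truth} (the connectome coupling that parameterizes the
#' subject's task covariance), generated jointly with symptoms and accuracy
#' from the configured latent correlation structure.
#'
#' Between-group mean differences are scaled by \code{effect_scale}; with
#' \code{effect_scale = 0} and all-zero \code{clustering_effect} every
#' variable has equal group means in expectation (the null configuration).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{data.frame} of class \code{"cohort_table"}, one row per
#'   subject, with the configuration seed in attribute \code{"seed"}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$group_sizes
  n <- sum(gs)
  ngrp <- length(gs)
  pr <- group_profiles()
  es <- config$effect_scale
  scale_means <- function(m) {
    m <- rep_len(m, ngrp)
    mean(m) + es * (m - mean(m))
  }
  with_seed(config$seed, {
    Z <- MASS::mvrnorm(n, rep(0, 5), config$latent_R)
    colnames(Z) <- colnames(config$latent_R)
    group <- factor(rep(names(gs), gs), levels = names(gs))
    gi <- as.integer(group)
    age <- round(rtruncnorm(n, scale_means(pr$age$m)[gi],
                            rep_len(pr$age$s, ngrp)[gi], 14, 45), 1)
    male_p <- pmin(pmax(scale_means(pr$male$m), 0), 1)
    sex <- ifelse(stats::runif(n) < male_p[gi], "M", "F")
    education <- round(rtruncnorm(n, scale_means(pr$edu$m)[gi],
                                  rep_len(pr$edu$s, ngrp)[gi], 3, 22), 1)
    neg <- pmin(pmax(pr$neg$m + pr$neg$s * Z[, "neg"], 7), 49)
    pos <- pmin(pmax(pr$pos$m + pr$pos$s * Z[, "pos"], 7), 49)
    if (!config$symptoms_all_groups) {
      mask <- group != names(gs)[1]
      neg[mask] <- NA_real_
      pos[mask] <- NA_real_
    }
    acc2 <- pmin(pmax(scale_means(pr$acc2$m)[gi] +
                        rep_len(pr$acc2$s, ngrp)[gi] * Z[, "acc"], 0), 1)
    z0 <- 0.6 * Z[, "acc"] + 0.8 * stats::rnorm(n)
    acc0 <- pmin(pmax(scale_means(pr$acc0$m)[gi] +
                        rep_len(pr$acc0$s, ngrp)[gi] * z0, 0), 1)
    fd_mu <- pmax(scale_means(pr$fd$m), 0.5)
    fd_size <- fd_mu[gi]^2 / pmax(rep_len(pr$fd$s, ngrp)[gi]^2 - fd_mu[gi], 1)
    fd <- stats::rnbinom(n, mu = fd_mu[gi], size = fd_size)
    coupling <- config$base_coupling *
      (1 + config$clustering_effect[gi] + config$coupling_sd * Z[, "topo"])
    coupling <- pmin(pmax(coupling, 0.05), 0.95)
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, sex = sex, education = education,
      neg_symptoms = round(neg, 1), pos_symptoms = round(pos, 1),
      acc_2back = acc2, acc_0back = acc0,
      fd_interp_count = as.integer(fd),
      liability_truth = Z[, "liab"],
      coupling_truth = as.numeric(coupling),
      stringsAsFactors = FALSE)
    attr(out, "seed") <- config$seed
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Weighted small-world ground-truth network
#'
#' Builds a Watts-Strogatz-style weighted network: a ring lattice where each
#' node connects to \code{neighbors} nodes on each side, rewired with
#' probability \code{rewire_p}, with edge weights drawn uniformly from
#' \code{weight_range}. Lower \code{rewire_p} gives higher clustering. When
#' \code{target_clustering} is supplied, \code{rewire_p} is solved from the
#' lattice decay law \code{C(p) = C(0) (1-p)^3} and the draw is retried
#' (up to 25 times) until the realized binary clustering is within
#' \code{tol} of the target.
#'
#' @param n_nodes node count.
#' @param neighbors lattice half-neighborhood size.
#' @param rewire_p rewiring probability in [0, 1].
#' @param weight_range uniform edge-weight range.
#' @param seed integer seed.
#' @param target_clustering optional target binary clustering coefficient.
#' @param tol tolerance on the achieved clustering (default 0.05).
#' @return object of class \code{"ground_truth_network"} with fields
#'   \code{n_nodes}, \code{adjacency}, \code{density}, \code{rewire_p},
#'   \code{achieved_clustering}, \code{target_clustering}.
#' @export
ground_truth_network <- function(n_nodes, neighbors = 6, rewire_p = 0.15,
                                 weight_range = c(0.5, 1), seed = 1L,
                                 target_clustering = NULL, tol = 0.05) {
  stopifnot(n_nodes > 2 * neighbors)
  lattice_C <- 3 * (neighbors - 1) / (2 * (2 * neighbors - 1))
  if (!is.null(target_clustering)) {
    if (target_clustering > lattice_C)
      stop(sprintf("target clustering %.3f exceeds the lattice maximum %.3f",
                   target_clustering, lattice_C), call. = FALSE)
    rewire_p <- 1 - (target_clustering / lattice_C)^(1 / 3)
  }
  with_seed(seed, {
    p_cur <- rewire_p
    for (attempt in 1:25) {
      g <- igraph::sample_smallworld(1, n_nodes, neighbors, p_cur)
      g <- igraph::simplify(g)
      achieved <- igraph::transitivity(g, type = "global")
      if (is.null(target_clustering) ||
          abs(achieved - target_clustering) <= tol) break
      # lattice decay law C(p) ~ C(0)(1-p)^3: adjust p toward the target
      ratio <- (target_clustering / max(achieved, 1e-6))^(1 / 3)
      p_cur <- min(max(1 - (1 - p_cur) * ratio, 0), 0.999)
    }
    rewire_p <- p_cur
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    ut <- upper.tri(A) & A != 0
    A[ut] <- stats::runif(sum(ut), weight_range[1], weight_range[2])
    A[lower.tri(A)] <- 0
    A <- A + t(A)
    structure(list(n_nodes = n_nodes, adjacency = A,
                   density = sum(A[upper.tri(A)] != 0) /
                     (n_nodes * (n_nodes - 1) / 2),
                   rewire_p = rewire_p,
                   achieved_clustering = achieved,
                   target_clustering = target_clustering),
              class = "ground_truth_network")
  })
}

# covariance I + c * S / rho(S); PD for c < 1, nearest-PD projected otherwise
coupling_covariance <- function(S_norm, coupling) {
  Sigma <- diag(nrow(S_norm)) + coupling * S_norm
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    Sigma <- as.matrix(Matrix::nearPD(Sigma, corr = FALSE)$mat)
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 1e-10)
      stop(sprintf(paste0("covariance not positive definite after nearest-PD ",
                          "projection (min eigenvalue %.3e, coupling %.3f)"),
                   ev_min, coupling), call. = FALSE)
  }
  Sigma
}

#' Generate synthetic ROI time series for a cohort
#'
#' For each subject, samples a nodes x volumes matrix from zero-mean
#' multivariate Gaussians, block by block: 2-back blocks use a covariance
#' \code{I + c_i * S_g} built from the subject's coupling \code{c_i}
#' (\code{coupling_truth}) and the group's ground-truth small-world network
#' \code{S_g} (spectrally normalized); 0-back blocks use a shared, heavily
#' rewired (less clustered) network at baseline coupling. Groups with a
#' positive \code{clustering_effect} get a more lattice-like 2-back network
#' (rewiring probability reduced by the factor \code{1 - effect/(1+effect)})
#' in addition to their elevated coupling. Blocks alternate 0-back / 2-back.
#'
#' @param cohort a \code{\link{generate_cohort}} table.
#' @param config the same \code{\link{sim_config}}.
#' @return named list of \code{\link{roi_timeseries}} objects (one per
#'   subject), with the per-group \code{\link{ground_truth_network}}s in
#'   attribute \code{"ground_truth"}.
#' @export
generate_timeseries <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "sim_config"))
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  n_nodes <- config$n_nodes
  nvpb <- config$n_volumes_per_block
  nb <- config$n_blocks
  groups <- levels(cohort$group)
  with_seed(config$seed + 1L, {
    # scale so the most negative eigenvalue is -1: I + c*S stays positive
    # definite for any coupling c < 1 while edge correlations stay as large
    # as the PD constraint allows
    norm_S <- function(gt) {
      S <- gt$adjacency
      S / abs(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
    }
    gt2 <- lapply(seq_along(groups), function(k) {
      eff <- config$clustering_effect[groups[k]]
      p <- config$ws_rewire_2back / (1 + max(eff, 0))
      ground_truth_network(n_nodes, config$ws_neighbors, p,
                           config$weight_range,
                           seed = config$seed + 100L + k)
    })
    names(gt2) <- groups
    gt0 <- ground_truth_network(n_nodes, config$ws_neighbors,
                                config$ws_rewire_0back, config$weight_range,
                                seed = config$seed + 200L)
    S2 <- lapply(gt2, norm_S)
    S0 <- norm_S(gt0)
    blocks <- data.frame(
      condition = rep(c("0back", "2back"), nb),
      start = seq(0, by = nvpb, length.out = 2 * nb),
      length = nvpb)
    out <- vector("list", nrow(cohort))
    names(out) <- cohort$subject_id
    for (i in seq_len(nrow(cohort))) {
      g <- as.character(cohort$group[i])
      c_i <- cohort$coupling_truth[i]
      R2 <- chol(coupling_covariance(S2[[g]], c_i))
      R0 <- chol(coupling_covariance(S0, config$base_coupling))
      X <- matrix(0, n_nodes, 2 * nb * nvpb)
      for (b in seq_len(nrow(blocks))) {
        Rc <- if (blocks$condition[b] == "2back") R2 else R0
        Zb <- matrix(stats::rnorm(nvpb * n_nodes), nvpb, n_nodes)
        X[, blocks$start[b] + seq_len(nvpb)] <- t(Zb %*% Rc)
      }
      out[[i]] <- roi_timeseries(cohort$subject_id[i], X,
                                 paste0("N", seq_len(n_nodes)), blocks)
    }
    attr(out, "ground_truth") <- list(task = gt2, control = gt0)
    attr(out, "seed") <- config$seed
    out
  })
}

#' Generate synthetic genotypes and GWAS weights
#'
#' Draws per-SNP allele frequencies, builds block-diagonal LD via a shared
#' latent factor per block, thresholds latent Gaussians at Hardy-Weinberg
#' quantiles to obtain dosages in \{0, 1, 2\}, injects missingness, and
#' assigns a configured number of causal SNPs nonzero log-odds-ratio
#' weights. Causal-SNP latents load on the cohort's \code{liability_truth}
#' (signed by the causal effect), so the true polygenic score correlates
#' positively with the latent liability. GWAS p-values are generated from
#' per-SNP z statistics consistent with the weight magnitudes.
#'
#' @param cohort a \code{\link{generate_cohort}} table.
#' @param n_snps number of SNPs (must be >= the configured causal count).
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{weights} (data.frame snp_id, effect_allele, OR, p),
#'   \code{true_prs} (per-subject score from the true causal effects), and
#'   \code{causal_ids}.
#' @export
generate_genetics <- function(cohort, n_snps, config) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "sim_config"))
  if (n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (n_snps < config$n_causal)
    stop(sprintf("n_snps (%d) < configured causal SNPs (%d)", n_snps,
                 config$n_causal), call. = FALSE)
  n <- nrow(cohort)
  with_seed(config$seed + 2L, {
    freq <- stats::runif(n_snps, 0.05, 0.5)
    block <- (seq_len(n_snps) - 1) %/% config$ld_block_size
    chrom <- block %% 22 + 1
    pos <- integer(n_snps)
    for (ch in unique(chrom))
      pos[chrom == ch] <- seq(50000L, by = 50000L, length.out = sum(chrom == ch))
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, n_snps, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
    beta <- numeric(n_snps)
    causal <- if (config$n_causal > 0) sample.int(n_snps, config$n_causal)
              else integer(0)
    beta[causal] <- stats::rnorm(length(causal), 0, 0.15)
    z <- beta / 0.03 + stats::rnorm(n_snps)
    pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    rho <- config$ld_latent_corr
    a <- numeric(n_snps)
    a[causal] <- config$genetic_coupling * sign(beta[causal])
    if (any(rho + a^2 >= 1))
      stop("ld_latent_corr + genetic_coupling^2 must be < 1", call. = FALSE)
    u <- matrix(stats::rnorm(n * length(unique(block))), n)
    colnames(u) <- as.character(unique(block))
    liab <- cohort$liability_truth
    dos <- matrix(0L, n, n_snps,
                  dimnames = list(cohort$subject_id,
                                  sprintf("rs%06d", seq_len(n_snps))))
    for (j in seq_len(n_snps)) {
      x <- sqrt(rho) * u[, as.character(block[j])] + a[j] * liab +
        sqrt(1 - rho - a[j]^2) * stats::rnorm(n)
      f <- freq[j]
      dos[, j] <- (x > stats::qnorm((1 - f)^2)) + (x > stats::qnorm(1 - f^2))
    }
    if (config$missing_rate > 0)
      dos[stats::runif(length(dos)) < config$missing_rate] <- NA_integer_
    snps <- data.frame(snp_id = colnames(dos), chrom = chrom, pos = pos,
                       effect_allele = ea, other_allele = oa,
                       stringsAsFactors = FALSE)
    geno <- genotype_matrix(cohort$subject_id, snps, dos)
    weights <- data.frame(snp_id = snps$snp_id, effect_allele = ea,
                          OR = exp(beta), p = pval, stringsAsFactors = FALSE)
    true_prs <- as.numeric(apply(dos, 1, function(r) {
      r[is.na(r)] <- 2 * freq[is.na(r)]
      sum(r * beta)
    }))
    list(genotypes = geno, weights = weights, true_prs = true_prs,
         causal_ids = snps$snp_id[causal])
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = ", "), "\n")
  cat(sprintf("  nodes: %d; blocks: %d x %d volumes per condition\n",
              x$n_nodes, x$n_blocks, x$n_volumes_per_block))
  cat(sprintf("  effect_scale: %.2f; clustering effect: %s\n", x$effect_scale,
              paste(sprintf("%s=%.2f", names(x$clustering_effect),
                            x$clustering_effect), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
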