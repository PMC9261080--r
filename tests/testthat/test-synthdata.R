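test_that("cohort generation respects configured group sizes and seed", {
  cfg <- sim_config(seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 99)
  expect_equal(as.vector(table(co$group)), c(27, 24, 48))
  expect_false(anyDuplicated(co$subject_id) > 0)
  expect_true(all(co$acc_2back >= 0 & co$acc_2back <= 1))
  expect_true(all(co$acc_0back >= 0 & co$acc_0back <= 1))
  expect_true(all(co$fd_interp_count >= 0))
  # symptom scores only for cases by default
  expect_true(all(is.na(co$neg_symptoms[co$group != "EOS"])))
  expect_true(all(!is.na(co$neg_symptoms[co$group == "EOS"])))
  expect_identical(co, generate_cohort(cfg))
  expect_error(sim_config(group_sizes = c(EOS = 0, SB = 5, HC = 5)),
               "positive")
})

test_that("null configuration equalizes group means in expectation", {
  diffs <- vapply(1:200, function(s) {
    cfg <- sim_config(group_sizes = c(EOS = 15, SB = 15, HC = 15),
                      effect_scale = 0,
                      clustering_effect = c(EOS = 0, SB = 0, HC = 0),
                      seed = s)
    co <- generate_cohort(cfg)
    m <- tapply(co$acc_2back, co$group, mean)
    a <- tapply(co$age, co$group, mean)
    c(m[["EOS"]] - m[["HC"]], a[["EOS"]] - a[["HC"]])
  }, numeric(2))
  # replicate-mean differences should be within Monte-Carlo error of zero
  expect_lt(abs(mean(diffs[1, ])), 3 * sd(diffs[1, ]) / sqrt(200))
  expect_lt(abs(mean(diffs[2, ])), 3 * sd(diffs[2, ]) / sqrt(200))
})

test_that("configured symptom-topology correlation is realized", {
  cors <- vapply(1:10, function(s) {
    cfg <- sim_config(group_sizes = c(EOS = 500, SB = 2, HC = 2), seed = s,
                      latent_corr = c(neg_topo = 0.4))
    co <- generate_cohort(cfg)
    eos <- co[co$group == "EOS", ]
    cor(eos$neg_symptoms, eos$coupling_truth)
  }, numeric(1))
  expect_true(all(abs(cors - 0.4) < 0.1))
})

test_that("ground-truth networks hit a requested clustering level", {
  gt <- ground_truth_network(80, neighbors = 5, target_clustering = 0.35,
                             seed = 2, tol = 0.05)
  expect_lt(abs(gt$achieved_clustering - 0.35), 0.05)
  expect_equal(gt$adjacency, t(gt$adjacency))
  expect_equal(diag(gt$adjacency), rep(0, 80))
  expect_true(all(gt$adjacency >= 0))
  expect_error(ground_truth_network(50, neighbors = 3, target_clustering = 0.9),
               "lattice maximum")
})

test_that("near-independent time series decorrelate at large volume counts", {
  cfg <- sim_config(group_sizes = c(EOS = 1, SB = 1, HC = 1), n_nodes = 30,
                    n_volumes_per_block = 625, n_blocks = 4,
                    base_coupling = 0.06,
                    clustering_effect = c(EOS = 0, SB = 0, HC = 0),
                    coupling_sd = 0, seed = 3)
  co <- generate_cohort(cfg)
  co$coupling_truth[] <- 0.05
  ts <- generate_timeseries(co, cfg)
  tb <- extract_condition_volumes(ts[[1]], "2back")
  expect_equal(ncol(tb$data), 2500)
  R <- cor(t(tb$data))
  expect_lt(max(abs(R[upper.tri(R)])), 0.12)
})

test_that("time-series generation is deterministic and block-structured", {
  cfg <- sim_config(group_sizes = c(EOS = 2, SB = 2, HC = 2), n_nodes = 20,
                    seed = 11)
  co <- generate_cohort(cfg)
  ts1 <- generate_timeseries(co, cfg)
  ts2 <- generate_timeseries(co, cfg)
  expect_identical(ts1[[1]]$data, ts2[[1]]$data)
  expect_identical(ts1[["S005"]]$data, ts2[["S005"]]$data)
  expect_equal(nrow(ts1[[1]]$blocks), 8)
  expect_equal(sort(unique(ts1[[1]]$blocks$condition)), c("0back", "2back"))
  expect_equal(ncol(ts1[[1]]$data), 240)
})

test_that("2-back covariance is more clustered than 0-back", {
  cfg <- sim_config(group_sizes = c(EOS = 1, SB = 1, HC = 1), n_nodes = 60,
                    n_volumes_per_block = 60, seed = 17)
  co <- generate_cohort(cfg)
  ts <- generate_timeseries(co, cfg)
  cl_of <- function(cond) {
    m <- fisher_z(correlation_matrix(extract_condition_volumes(ts[[1]], cond)))
    W <- threshold_proportional(pmax(m$weights, 0), 0.2)
    clustering_weighted(W)$C
  }
  expect_gt(cl_of("2back"), cl_of("0back"))
})

test_that("genotypes follow Hardy-Weinberg proportions at the drawn frequency", {
  cfg <- sim_config(group_sizes = c(EOS = 5000, SB = 2, HC = 2), n_causal = 0,
                    missing_rate = 0, seed = 23)
  co <- generate_cohort(cfg)
  gen <- generate_genetics(co, n_snps = 12, cfg)
  d <- gen$genotypes$dosages
  for (j in c(1, 5, 9)) {
    f <- mean(d[, j]) / 2
    obs <- c(mean(d[, j] == 0), mean(d[, j] == 1), mean(d[, j] == 2))
    expect_equal(obs, c((1 - f)^2, 2 * f * (1 - f), f^2), tolerance = 0.03)
  }
})

test_that("null GWAS weights give a zero-variance polygenic score", {
  cfg <- sim_config(group_sizes = c(EOS = 30, SB = 2, HC = 2), n_causal = 0,
                    seed = 31)
  co <- generate_cohort(cfg)
  gen <- generate_genetics(co, n_snps = 40, cfg)
  expect_true(all(gen$weights$OR == 1))
  sc <- prs_score(gen$genotypes, gen$weights, p_threshold = 1)
  expect_equal(as.numeric(sc), rep(0, 34))
  expect_equal(sd(gen$true_prs), 0)
})

test_that("causal effects make the true score track the latent liability", {
  cors <- vapply(1:20, function(s) {
    cfg <- sim_config(group_sizes = c(EOS = 500, SB = 2, HC = 2),
                      n_causal = 50, seed = 100 + s)
    co <- generate_cohort(cfg)
    gen <- generate_genetics(co, n_snps = 400, cfg)
    cor(gen$true_prs, co$liability_truth)
  }, numeric(1))
  expect_gte(mean(cors > 0), 0.95)
})

test_that("LD is concentrated within blocks", {
  cfg <- sim_config(group_sizes = c(EOS = 800, SB = 2, HC = 2), n_causal = 0,
                    ld_block_size = 5, missing_rate = 0, seed = 41)
  co <- generate_cohort(cfg)
  gen <- generate_genetics(co, n_snps = 20, cfg)
  within <- ld_r2(gen$genotypes, 1, 2)       # same block
  between <- ld_r2(gen$genotypes, 1, 6)      # different blocks
  expect_gt(within, 0.2)
  expect_lt(between, 0.05)
})

test_that("undersized SNP panels are rejected", {
  cfg <- sim_config(group_sizes = c(EOS = 5, SB = 2, HC = 2), n_causal = 50)
  co <- generate_cohort(cfg)
  expect_error(generate_genetics(co, n_snps = 10, cfg), "causal")
})
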