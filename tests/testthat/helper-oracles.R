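# Independent brute-force oracles used to validate the package's graph and
# statistics code. These deliberately re-derive each quantity from its
# definition with naive loops, sharing no code with the implementation.

# Onnela weighted clustering by exhaustive triple enumeration
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) if (j != h)
      s <- s + (Wh[i, j] * Wh[j, h] * Wh[h, i])^(1 / 3)
    ci[i] <- s / (k * (k - 1))
  }
  list(ci = ci, C = mean(ci))
}

# all-pairs shortest paths on lengths 1/w by Floyd-Warshall
oracle_path_length <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

# proportional threshold by explicit sort of the edge list
oracle_threshold <- function(W, d) {
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
  df <- df[order(-df$w, df$i, df$j), ]
  k <- floor(d * n * (n - 1) / 2)
  df <- df[seq_len(min(k, nrow(df))), ]
  df <- df[df$w != 0, ]
  out <- matrix(0, n, n)
  out[cbind(df$i, df$j)] <- df$w
  out + t(out)
}

# Benjamini-Hochberg walked from the definition
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min((m / seq(i, m)) * ps[seq(i, m)])), numeric(1))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  passed <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(passed) > 0) reject[o[seq_len(max(passed))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

# greedy LD clumping from the definition, with r2 computed inline
oracle_clump <- function(dosages, meta, p, r2_max = 0.2, window_kb = 500) {
  ord <- order(p, meta$chrom, meta$pos)
  kept <- integer(0)
  for (k in ord) {
    ok <- TRUE
    for (m in kept) {
      if (meta$chrom[m] != meta$chrom[k]) next
      if (abs(meta$pos[m] - meta$pos[k]) > window_kb * 1000) next
      x <- dosages[, k]; y <- dosages[, m]
      cc <- !is.na(x) & !is.na(y)
      if (sum(cc) < 2 || stats::var(x[cc]) == 0 || stats::var(y[cc]) == 0) next
      if (stats::cor(x[cc], y[cc])^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, k)
  }
  sort(meta$snp_id[kept])
}

# random symmetric nonnegative weighted graph for fixture sets
random_weighted_graph <- function(n, p_edge = 0.5, seed = 1) {
  wmtopo:::with_seed(seed, {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    edges <- stats::runif(sum(ut)) < p_edge
    w <- numeric(sum(ut))
    w[edges] <- stats::runif(sum(edges), 0.2, 1)
    W[ut] <- w
    W + t(W)
  })
}

# small-graph fixture set shared by oracle-equivalence tests
fixture_graphs <- function() {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  tri_pendant <- matrix(0, 4, 4)
  tri_pendant[1, 2] <- 1.0; tri_pendant[1, 3] <- 0.5; tri_pendant[2, 3] <- 0.5
  tri_pendant[3, 4] <- 0.7
  tri_pendant <- tri_pendant + t(tri_pendant)
  star5 <- matrix(0, 5, 5); star5[1, 2:5] <- 0.8; star5 <- star5 + t(star5)
  complete5 <- matrix(0.6, 5, 5); diag(complete5) <- 0
  sizes <- rep(4:8, length.out = 12)
  rnd <- lapply(1:12, function(s)
    random_weighted_graph(sizes[s], p_edge = 0.6, seed = 100 + s))
  c(list(path3 = path3, tri_pendant = tri_pendant, star5 = star5,
         complete5 = complete5), rnd)
}

extdata <- function(...) system.file("extdata", ..., package = "wmtopo")
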