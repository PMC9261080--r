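#' Proportional density thresholding of a weighted network
#'
#' Retains the strongest edges of a symmetric weighted adjacency matrix so
#' that the resulting graph has the requested connection density, i.e. the
#' fraction \code{d} of all possible \code{n(n-1)/2} edges. Retained weights
#' are unchanged; all other entries are set to zero.
#'
#' Ties at the cut position are broken deterministically: edges are ordered
#' by weight (descending), then by node-pair index (lexicographic), and the
#' first \code{floor(d * n(n-1)/2)} edges are kept.
#'
#' @param W symmetric numeric matrix with zero diagonal.
#' @param d target density in (0, 1].
#' @return symmetric matrix of the same dimension with exactly
#'   \code{floor(d * n(n-1)/2)} nonzero upper-triangular entries (fewer only
#'   if \code{W} has fewer nonzero edges than that).
#' @export
threshold_proportional <- function(W, d) {
  check_adjacency(W)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0 || d > 1)
    stop("density `d` must be a single value in (0, 1]", call. = FALSE)
  n <- nrow(W)
  ut <- upper.tri(W)
  idx <- which(ut, arr.ind = TRUE)
  w <- W[ut]
  k <- floor(d * n * (n - 1) / 2)
  ord <- order(-w, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(min(k, length(ord)))]
  # drop edges that are exactly zero (absent) even if ranked within k
  keep <- keep[w[keep] != 0]
  out <- matrix(0, n, n, dimnames = dimnames(W))
  out[cbind(idx[keep, 1L], idx[keep, 2L])] <- w[keep]
  out + t(out)
}

#' Onnela weighted clustering coefficient
#'
#' Per-node weighted clustering after scaling all weights by the network-wide
#' maximum: \code{c_i = sum_{jh} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))},
#' where \code{k_i} is the binary degree. Nodes with degree < 2 get
#' \code{c_i = 0}. The network mean \code{C} averages over all nodes.
#'
#' @param W symmetric nonnegative matrix, zero diagonal.
#' @return list with \code{ci} (per-node values) and \code{C} (their mean).
#' @export
clustering_weighted <- function(W) {
  check_adjacency(W)
  if (any(W < 0))
    stop("clustering_weighted requires nonnegative weights; ",
         "apply a negative-edge policy first", call. = FALSE)
  wmax <- max(W)
  n <- nrow(W)
  if (wmax == 0) return(list(ci = rep(0, n), C = 0))
  Wh <- (W / wmax)^(1 / 3)
  # diag(Wh^3) counts closed weighted triangles through each node (x2)
  tri <- diag(Wh %*% Wh %*% Wh)
  k <- colSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  list(ci = as.numeric(ci), C = mean(ci))
}

#' Weighted characteristic path length
#'
#' Maps each edge weight to a length \code{1/w}, computes all-pairs shortest
#' path lengths, and averages over connected (finite-distance) node pairs.
#' Disconnected pairs are excluded from the mean; their count is attached as
#' the \code{"n_disconnected_pairs"} attribute.
#'
#' @param W symmetric nonnegative matrix, zero diagonal, at least one edge.
#' @return scalar mean shortest path length over connected pairs.
#' @export
characteristic_path_length <- function(W) {
  check_adjacency(W)
  if (any(W < 0))
    stop("characteristic_path_length requires nonnegative weights", call. = FALSE)
  if (all(W == 0)) stop("graph has no edges", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  d <- D[upper.tri(D)]
  finite <- is.finite(d)
  L <- mean(d[finite])
  attr(L, "n_disconnected_pairs") <- sum(!finite)
  L
}

#' Degree-preserving null ensemble for a weighted graph
#'
#' Builds \code{k} random reference networks that preserve the node count,
#' edge count, and exact degree sequence of the source graph: the binary
#' topology is rewired by double-edge swaps (about \code{swap_factor}
#' attempted swaps per edge), then the source's multiset of edge weights is
#' randomly reassigned to the rewired edges. On a complete graph, where no
#' swap can change the topology, the nulls are weight-permuted copies of the
#' original (with a warning).
#'
#' @param W symmetric nonnegative weighted adjacency with >= 4 edges.
#' @param k number of null networks (default 20).
#' @param seed integer seed controlling the ensemble.
#' @param swap_factor attempted swaps per edge (default 10).
#' @return object of class \code{"null_ensemble"}: list with \code{graphs}
#'   (list of weight matrices), \code{k}, and \code{seed}.
#' @export
null_ensemble <- function(W, k = 20, seed = 1L, swap_factor = 10) {
  check_adjacency(W)
  n <- nrow(W)
  ut <- upper.tri(W)
  weights <- W[ut][W[ut] != 0]
  n_edges <- length(weights)
  if (n_edges < 4) stop("null_ensemble needs a graph with >= 4 edges", call. = FALSE)
  complete <- n_edges == n * (n - 1) / 2
  if (complete)
    warning("complete graph cannot be rewired; nulls are weight-permuted copies",
            call. = FALSE)
  g0 <- igraph::graph_from_adjacency_matrix((W != 0) * 1, mode = "undirected",
                                            diag = FALSE)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  graphs <- vector("list", k)
  for (i in seq_len(k)) {
    gi <- if (complete) g0 else
      igraph::rewire(g0, igraph::keeping_degseq(niter = swap_factor * n_edges))
    el <- igraph::as_edgelist(gi, names = FALSE)
    M <- matrix(0, n, n, dimnames = dimnames(W))
    M[el] <- sample(weights)
    graphs[[i]] <- M + t(M)
  }
  structure(list(graphs = graphs, k = k, seed = seed),
            class = "null_ensemble")
}

#' Small-world indices normalized against a null ensemble
#'
#' Computes the weighted clustering coefficient \code{C} and characteristic
#' path length \code{L} of the network, the ensemble means \code{C_null} and
#' \code{L_null} over the nulls, and the normalized indices
#' \code{gamma = C / C_null}, \code{lambda = L / L_null}, and the
#' small-worldness \code{sigma = gamma / lambda}.
#'
#' @param W thresholded weighted adjacency matrix.
#' @param nulls a \code{\link{null_ensemble}} derived from \code{W}.
#' @return object of class \code{"global_topology"}: list with fields
#'   \code{C}, \code{L}, \code{C_null}, \code{L_null}, \code{gamma},
#'   \code{lambda}, \code{sigma}, and \code{ci} (per-node clustering).
#' @export
small_world_indices <- function(W, nulls) {
  stopifnot(inherits(nulls, "null_ensemble"))
  cl <- clustering_weighted(W)
  L <- as.numeric(characteristic_path_length(W))
  C_null <- mean(vapply(nulls$graphs, function(M) clustering_weighted(M)$C,
                        numeric(1)))
  L_null <- mean(vapply(nulls$graphs,
                        function(M) as.numeric(characteristic_path_length(M)),
                        numeric(1)))
  if (C_null == 0) stop("degenerate null ensemble: C_null = 0", call. = FALSE)
  if (L_null == 0) stop("degenerate null ensemble: L_null = 0", call. = FALSE)
  gamma <- cl$C / C_null
  lambda <- L / L_null
  structure(list(C = cl$C, L = L, C_null = C_null, L_null = L_null,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 ci = cl$ci),
            class = "global_topology")
}

#' Default density grid
#'
#' Densities 0.10 to 0.50 in steps of 0.02 (21 points).
#' @return numeric vector of 21 densities.
#' @export
default_densities <- function() seq(0.10, 0.50, by = 0.02)

#' Metric-versus-density curves for one connectome
#'
#' Applies the negative-edge policy, thresholds the matrix at every density
#' of the grid, and computes null-normalized small-world indices at each,
#' giving per-subject curves of C, L, gamma, lambda and sigma plus a
#' node-by-density matrix of regional clustering coefficients.
#'
#' @param mat a \code{connectome} object (see \code{\link{correlation_matrix}})
#'   or a bare symmetric weight matrix.
#' @param densities strictly increasing grid within (0, 1].
#' @param k_null nulls per density (default 20).
#' @param seed integer seed for the null ensembles.
#' @param negative_policy how to treat negative weights before thresholding:
#'   \code{"zero"} (set to 0, default) or \code{"abs"} (absolute value).
#' @return object of class \code{"metric_curve"}: list with \code{subject_id},
#'   \code{curve} (data.frame density, C, L, C_null, L_null, gamma, lambda,
#'   sigma) and \code{regional} (nodes x densities matrix of c_i).
#' @export
metric_curves <- function(mat, densities = default_densities(), k_null = 20,
                          seed = 1L, negative_policy = c("zero", "abs")) {
  negative_policy <- match.arg(negative_policy)
  subject_id <- if (inherits(mat, "connectome")) mat$subject_id else NA_character_
  W <- if (inherits(mat, "connectome")) mat$weights else mat
  check_adjacency(W)
  if (any(densities <= 0) || any(densities > 1) ||
      any(diff(densities) <= 0))
    stop("densities must be strictly increasing within (0, 1]", call. = FALSE)
  W <- switch(negative_policy, zero = pmax(W, 0), abs = abs(W))
  n_dens <- length(densities)
  cols <- c("C", "L", "C_null", "L_null", "gamma", "lambda", "sigma")
  curve <- matrix(NA_real_, n_dens, length(cols), dimnames = list(NULL, cols))
  regional <- matrix(NA_real_, nrow(W), n_dens,
                     dimnames = list(rownames(W), NULL))
  for (j in seq_len(n_dens)) {
    d <- densities[j]
    gt <- tryCatch({
      Wd <- threshold_proportional(W, d)
      nulls <- null_ensemble(Wd, k = k_null, seed = seed + j)
      small_world_indices(Wd, nulls)
    }, error = function(e) {
      stop(sprintf("metric_curves failed for subject '%s' at density %.3f: %s",
                   subject_id, d, conditionMessage(e)), call. = FALSE)
    })
    curve[j, ] <- c(gt$C, gt$L, gt$C_null, gt$L_null,
                    gt$gamma, gt$lambda, gt$sigma)
    regional[, j] <- gt$ci
  }
  structure(list(subject_id = subject_id,
                 curve = data.frame(density = densities, curve),
                 regional = regional),
            class = "metric_curve")
}

#' @export
print.global_topology <- function(x, ...) {
  cat("Global weighted topology\n")
  cat(sprintf("  C = %.4f  (C_null = %.4f)  gamma  = %.4f\n",
              x$C, x$C_null, x$gamma))
  cat(sprintf("  L = %.4f  (L_null = %.4f)  lambda = %.4f\n",
              x$L, x$L_null, x$lambda))
  cat(sprintf("  sigma = gamma/lambda = %.4f\n", x$sigma))
  invisible(x)
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("Metric curves for subject '%s' over %d densities [%.2f, %.2f]\n",
              x$subject_id, nrow(x$curve), min(x$curve$density),
              max(x$curve$density)))
  print(utils::head(x$curve, 3), row.names = FALSE)
  if (nrow(x$curve) > 3) cat("  ...\n")
  invisible(x)
}
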