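# internal validation and RNG helpers

check_adjacency <- function(W) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W))
    stop("expected a square numeric matrix", call. = FALSE)
  if (any(!is.finite(W)))
    stop("adjacency matrix contains non-finite entries", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10)
    stop("adjacency matrix is not symmetric", call. = FALSE)
  if (any(diag(W) != 0))
    stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  invisible(TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# run expr under a local seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

# truncated-normal draws by rejection with a cap on resampling rounds
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
  }
  pmin(pmax(x, lower), upper)
}
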