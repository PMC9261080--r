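#' ROI time-series object
#'
#' Container for one subject's region-of-interest time series together with
#' the task block design. Volume indices are 0-based and block intervals are
#' half-open: a block starting at \code{start} with \code{length} volumes
#' covers columns \code{start .. start+length-1} (0-based).
#'
#' @param subject_id subject identifier.
#' @param data nodes x volumes numeric matrix.
#' @param node_ids ordered node labels (default rownames or N1..Nn).
#' @param blocks data.frame with columns \code{condition}, \code{start}
#'   (0-based volume index), \code{length}.
#' @return object of class \code{"roi_timeseries"}.
#' @export
roi_timeseries <- function(subject_id, data, node_ids = NULL, blocks) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (is.null(node_ids))
    node_ids <- if (!is.null(rownames(data))) rownames(data) else
      paste0("N", seq_len(nrow(data)))
  stopifnot(length(node_ids) == nrow(data))
  req <- c("condition", "start", "length")
  if (!is.data.frame(blocks) || !all(req %in% names(blocks)))
    stop("blocks must be a data.frame with columns condition, start, length",
         call. = FALSE)
  if (any(blocks$start < 0) || any(blocks$length <= 0) ||
      any(blocks$start + blocks$length > ncol(data)))
    stop("block intervals must lie within [0, volumes)", call. = FALSE)
  ends <- blocks$start + blocks$length
  ord <- order(blocks$start)
  if (any(blocks$start[ord][-1] < ends[ord][-nrow(blocks)]))
    stop("block intervals overlap", call. = FALSE)
  rownames(data) <- node_ids
  structure(list(subject_id = subject_id, data = data, node_ids = node_ids,
                 blocks = blocks[order(blocks$start), , drop = FALSE]),
            class = "roi_timeseries")
}

#' Concatenate the volumes of one task condition
#'
#' Extracts, in temporal order, all volumes belonging to blocks of the named
#' condition (e.g. all 2-back blocks of an n-back run) and returns a new
#' time-series object whose block design describes the concatenated blocks.
#'
#' @param ts a \code{\link{roi_timeseries}} object.
#' @param condition block condition label to keep.
#' @return \code{roi_timeseries} with only the requested condition's volumes.
#' @export
extract_condition_volumes <- function(ts, condition) {
  stopifnot(inherits(ts, "roi_timeseries"))
  b <- ts$blocks
  sel <- b$condition == condition
  if (!any(sel))
    stop(sprintf("condition '%s' not present; available: %s", condition,
                 paste(unique(b$condition), collapse = ", ")), call. = FALSE)
  b <- b[sel, , drop = FALSE]
  cols <- unlist(lapply(seq_len(nrow(b)),
                        function(i) b$start[i] + seq_len(b$length[i])))
  new_blocks <- data.frame(condition = b$condition,
                           start = cumsum(c(0, b$length[-nrow(b)])),
                           length = b$length)
  roi_timeseries(ts$subject_id, ts$data[, cols, drop = FALSE],
                 ts$node_ids, new_blocks)
}

#' Pearson correlation connectome
#'
#' Computes the node-by-node Pearson correlation matrix of a subject's time
#' series. The diagonal is set to zero so the result can feed proportional
#' thresholding directly.
#'
#' @param ts a \code{\link{roi_timeseries}} object with >= 3 volumes.
#' @return object of class \code{"connectome"}: list with \code{subject_id},
#'   \code{weights} (symmetric, zero diagonal, r scale), \code{node_ids},
#'   \code{scale = "r"}, \code{corrected = FALSE}.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$data) < 3)
    stop("need at least 3 volumes to correlate", call. = FALSE)
  v <- apply(ts$data, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance node(s): ",
         paste(ts$node_ids[v == 0], collapse = ", "), call. = FALSE)
  R <- stats::cor(t(ts$data))
  diag(R) <- 0
  R <- (R + t(R)) / 2
  structure(list(subject_id = ts$subject_id, weights = R,
                 node_ids = ts$node_ids, scale = "r", corrected = FALSE),
            class = "connectome")
}

#' Fisher z transformation of a correlation connectome
#'
#' Applies \code{z = atanh(r)} elementwise. Correlations at exactly +/-1
#' (possible on degenerate simulated inputs) are clipped to
#' \code{+/-(1 - 1e-7)} first when \code{clip = TRUE} (with a warning);
#' with \code{clip = FALSE} they are an error.
#'
#' @param m a \code{connectome} on the r scale.
#' @param clip clip |r| >= 1 before transforming (default TRUE).
#' @return the connectome on the Fisher-z scale (\code{scale = "z"}).
#' @export
fisher_z <- function(m, clip = TRUE) {
  stopifnot(inherits(m, "connectome"))
  if (!identical(m$scale, "r"))
    stop("fisher_z expects an r-scale connectome", call. = FALSE)
  R <- m$weights
  if (any(abs(R) >= 1)) {
    if (!clip) stop("correlations with |r| >= 1 present and clip = FALSE",
                    call. = FALSE)
    warning(sprintf("%d correlation(s) with |r| >= 1 clipped to +/-(1 - 1e-7)",
                    sum(abs(R) >= 1)), call. = FALSE)
    R <- pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7)
  }
  Z <- atanh(R)
  diag(Z) <- 0
  m$weights <- Z
  m$scale <- "z"
  m
}

#' Remove demographic covariate effects from connectome edges
#'
#' For every edge, fits an ordinary least-squares model of the edge weight
#' across subjects on age, sex and education (plus intercept) and replaces
#' the weights by the residuals with the grand mean re-added, so the weight
#' scale stays interpretable for proportional thresholding. Sex is encoded
#' 0/1 (residuals are invariant to the affine coding).
#'
#' @param matrices list of \code{connectome} objects (same node set, one per
#'   covariate row).
#' @param covariates data.frame with columns \code{age}, \code{sex},
#'   \code{education}, rows in the same order as \code{matrices} (or matched
#'   on a \code{subject_id} column when present).
#' @return list of corrected \code{connectome} objects
#'   (\code{corrected = TRUE}).
#' @export
regress_covariates <- function(matrices, covariates) {
  stopifnot(is.list(matrices), all(vapply(matrices, inherits, TRUE, "connectome")))
  n <- length(matrices)
  req <- c("age", "sex", "education")
  if (!all(req %in% names(covariates)))
    stop("covariates must contain columns age, sex, education", call. = FALSE)
  if ("subject_id" %in% names(covariates)) {
    ids <- vapply(matrices, `[[`, character(1), "subject_id")
    pos <- match(ids, covariates$subject_id)
    if (any(is.na(pos)))
      stop("covariate rows missing for subject(s): ",
           paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
    covariates <- covariates[pos, , drop = FALSE]
  }
  if (nrow(covariates) != n)
    stop("one covariate row required per subject", call. = FALSE)
  if (n <= 4)
    stop("need more subjects than covariates (+ intercept) to residualize",
         call. = FALSE)
  sex <- covariates$sex
  if (!is.numeric(sex)) sex <- as.numeric(factor(sex)) - 1
  X <- cbind(intercept = 1, age = covariates$age, sex = sex,
             education = covariates$education)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nn <- nrow(matrices[[1]]$weights)
  ut <- upper.tri(matrices[[1]]$weights)
  E <- t(vapply(matrices, function(m) m$weights[ut], numeric(sum(ut))))
  resid <- E - X %*% qr.coef(qx, E)
  resid <- sweep(resid, 2, colMeans(E), `+`)
  lapply(seq_len(n), function(i) {
    m <- matrices[[i]]
    Wn <- matrix(0, nn, nn, dimnames = dimnames(m$weights))
    Wn[ut] <- resid[i, ]
    m$weights <- Wn + t(Wn)
    m$corrected <- TRUE
    m
  })
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome '%s': %d nodes, %s scale%s\n", x$subject_id,
              nrow(x$weights), x$scale,
              if (isTRUE(x$corrected)) ", covariate-corrected" else ""))
  invisible(x)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d nodes x %d volumes, %d blocks (%s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), nrow(x$blocks),
              paste(unique(x$blocks$condition), collapse = "/")))
  invisible(x)
}
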