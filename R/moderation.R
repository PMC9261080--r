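#' Pairwise correlation screen
#'
#' Pearson correlation and two-sided p-value for every unordered pair of the
#' given variables, using pairwise-complete observations. Pairs involving a
#' constant variable are returned with \code{r = NA} and flagged
#' \code{undefined} rather than silently zeroed.
#'
#' @param table data.frame of per-subject variables.
#' @param vars columns to screen (default: all numeric columns).
#' @return data.frame with columns \code{var1}, \code{var2}, \code{r},
#'   \code{p}, \code{n}, \code{undefined}.
#' @export
correlation_screen <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  stopifnot(length(vars) >= 2, all(vars %in% names(table)))
  out <- NULL
  for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    x <- table[[vars[i]]]; y <- table[[vars[j]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3)
      stop(sprintf("fewer than 3 complete pairs for %s vs %s",
                   vars[i], vars[j]), call. = FALSE)
    undef <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
    if (undef) {
      row <- data.frame(var1 = vars[i], var2 = vars[j], r = NA_real_,
                        p = NA_real_, n = n, undefined = TRUE)
    } else {
      ct <- stats::cor.test(x[ok], y[ok])
      row <- data.frame(var1 = vars[i], var2 = vars[j],
                        r = unname(ct$estimate), p = ct$p.value, n = n,
                        undefined = FALSE)
    }
    out <- rbind(out, row)
  }
  out
}

ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("perfect collinearity in design; degenerate term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df)
  list(coef = beta, se = se, p = p, df = df)
}

boot_cis <- function(est, boots, level = 0.95) {
  a <- (1 - level) / 2
  out <- lapply(seq_along(est), function(k) {
    b <- boots[, k]
    perc <- stats::quantile(b, c(a, 1 - a), names = FALSE)
    # bias-corrected (BC) bootstrap: shift percentile positions by z0
    prop <- mean(b < est[k]) + 0.5 * mean(b == est[k])
    prop <- min(max(prop, 1 / (length(b) + 1)), length(b) / (length(b) + 1))
    z0 <- stats::qnorm(prop)
    za <- stats::qnorm(c(a, 1 - a))
    bc <- stats::quantile(b, stats::pnorm(2 * z0 + za), names = FALSE)
    c(perc_lo = perc[1], perc_hi = perc[2], bc_lo = bc[1], bc_hi = bc[2])
  })
  do.call(rbind, out)
}

fit_moderation <- function(X_raw, Y, terms, n_boot, seed, call) {
  n <- nrow(X_raw)
  fit <- ols_fit(X_raw, Y)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, ncol(X_raw))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- tryCatch(qr.coef(qr(X_raw[idx, , drop = FALSE]), Y[idx]),
                   error = function(e) rep(NA_real_, ncol(X_raw)))
    boots[b, ] <- cf
  }
  ok <- stats::complete.cases(boots)
  cis <- boot_cis(fit$coef, boots[ok, , drop = FALSE])
  coefs <- data.frame(term = terms, estimate = as.numeric(fit$coef),
                      se = fit$se, p = as.numeric(fit$p),
                      ci_perc_lo = cis[, 1], ci_perc_hi = cis[, 2],
                      ci_bc_lo = cis[, 3], ci_bc_hi = cis[, 4],
                      row.names = NULL)
  structure(list(coefficients = coefs, n = n, n_boot = n_boot,
                 n_boot_ok = sum(ok), seed = seed, df = fit$df, call = call),
            class = "moderation_fit")
}

#' Single-moderator interaction model with bootstrap inference
#'
#' Ordinary least squares fit of
#' \code{Y ~ b0 + bX X + bW W + beta (X * W)} with X and W mean-centered
#' before the product is formed. Coefficient confidence intervals come from
#' a case-resampling bootstrap (percentile and bias-corrected intervals both
#' reported); analytic OLS p-values are reported alongside.
#'
#' @param X predictor (e.g. synthesized polygenic score).
#' @param W moderator (e.g. negative-symptom burden or small-worldness).
#' @param Y outcome (e.g. 2-back accuracy).
#' @param n_boot bootstrap draws (default 5000).
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{"moderation_fit"}; the interaction row is
#'   named \code{"X:W"}.
#' @export
moderation_model1 <- function(X, W, Y, n_boot = 5000, seed = 1L) {
  ok <- stats::complete.cases(X, W, Y)
  X <- X[ok]; W <- W[ok]; Y <- Y[ok]
  if (length(Y) < 10) stop("need >= 10 complete cases", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  Xc <- X - mean(X); Wc <- W - mean(W)
  D <- cbind(`(Intercept)` = 1, X = Xc, W = Wc, `X:W` = Xc * Wc)
  fit_moderation(D, Y, colnames(D), n_boot, seed, match.call())
}

#' Dual-moderator interaction model with bootstrap inference
#'
#' OLS fit of \code{Y ~ b0 + bX X + b1 W1 + b2 W2 + beta1 (X W1) +
#' beta2 (X W2)} with mean-centering of X and both moderators before the
#' products are formed; bootstrap inference as in
#' \code{\link{moderation_model1}}.
#'
#' @param X predictor.
#' @param W1,W2 the two moderators (must not be identical).
#' @param Y outcome.
#' @param n_boot bootstrap draws (default 5000).
#' @param seed integer seed.
#' @return a \code{"moderation_fit"} with interaction rows \code{"X:W1"}
#'   and \code{"X:W2"}.
#' @export
moderation_model2 <- function(X, W1, W2, Y, n_boot = 5000, seed = 1L) {
  ok <- stats::complete.cases(X, W1, W2, Y)
  X <- X[ok]; W1 <- W1[ok]; W2 <- W2[ok]; Y <- Y[ok]
  if (length(Y) < 10) stop("need >= 10 complete cases", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  if (isTRUE(all.equal(W1, W2)))
    stop("perfect collinearity in design; degenerate term(s): W2 (identical to W1)",
         call. = FALSE)
  Xc <- X - mean(X); W1c <- W1 - mean(W1); W2c <- W2 - mean(W2)
  D <- cbind(`(Intercept)` = 1, X = Xc, W1 = W1c, W2 = W2c,
             `X:W1` = Xc * W1c, `X:W2` = Xc * W2c)
  fit_moderation(D, Y, colnames(D), n_boot, seed, match.call())
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("Moderation model (n = %d, %d bootstrap draws, seed %d)\n",
              x$n, x$n_boot, x$seed))
  print(x$coefficients[, c("term", "estimate", "p", "ci_bc_lo", "ci_bc_hi")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.moderation_fit <- function(object, ...) {
  cat(sprintf("Moderation model: %s\n", deparse(object$call)))
  cat(sprintf("n = %d complete cases; residual df = %d; %d/%d bootstrap draws usable\n",
              object$n, object$df, object$n_boot_ok, object$n_boot))
  print(object$coefficients, row.names = FALSE, digits = 4)
  invisible(object$coefficients)
}

#' @export
coef.moderation_fit <- function(object, ...)
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
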