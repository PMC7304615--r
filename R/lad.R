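# Least-absolute-deviations (median, tau = 0.5) regression.
#
# Written in-package because no quantile-regression fit is available in the
# dependency stack. The fit is iteratively reweighted least squares on the
# smoothed |r| objective; inference follows the classical iid route for
# quantile regression (sparsity estimated by a difference quotient of the
# residual quantile function at the Hall-Sheather bandwidth), with a pairs
# bootstrap fallback for sparse designs where the sparsity estimate is
# unusable.

lad_fit <- function(y, X, tol = 1e-6, maxit = 60L) {
  X <- as.matrix(X)
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design in LAD fit")
  b <- qr.coef(qx, y)
  scale0 <- stats::mad(y - X %*% b) + stats::sd(y) * 1e-6 + 1e-12
  delta <- 1e-8 * scale0
  conv <- FALSE
  for (it in seq_len(maxit)) {
    r <- as.numeric(y - X %*% b)
    ws <- 1 / sqrt(pmax(abs(r), delta))
    fit <- .lm.fit(X * ws, y * ws)
    b_new <- numeric(ncol(X))
    b_new[fit$pivot] <- fit$coefficients
    # tol is on the coefficient sup-norm, well below any usable se scale
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new; conv <- TRUE; break
    }
    b <- b_new
  }
  list(coefficients = b, residuals = as.numeric(y - X %*% b),
       converged = conv, iterations = it)
}

# Hall-Sheather bandwidth for tau = 0.5 at level alpha = 0.05
hall_sheather_bw <- function(n, tau = 0.5, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  q <- stats::qnorm(tau)
  n^(-1 / 3) * z^(2 / 3) *
    ((1.5 * stats::dnorm(q)^2) / (2 * q^2 + 1))^(1 / 3)
}

# sparsity s(tau) = 1/f(F^-1(tau)) from the empirical residual quantiles
lad_sparsity <- function(res, tau = 0.5) {
  n <- length(res)
  h <- hall_sheather_bw(n, tau)
  if (tau + h >= 1 || tau - h <= 0) return(NA_real_)
  qs <- stats::quantile(res, c(tau + h, tau - h), names = FALSE, type = 7)
  (qs[1] - qs[2]) / (2 * h)
}

#' Median (quantile tau = 0.5) regression test for the genotype effect
#'
#' Fits least-absolute-deviations regression of the trait on
#' `[covariates, genotype]` and tests the genotype coefficient. Standard
#' errors use the iid sparsity estimate by default; when the design is sparse
#' (few carriers) or the sparsity estimate degenerates, a pairs bootstrap is
#' used instead (the result is flagged `"bootstrap"`).
#'
#' @inheritParams wald_test
#' @param bootstrap Force (`TRUE`) or forbid (`FALSE`) the bootstrap;
#'   `NULL` (default) switches automatically.
#' @param B Bootstrap replicates.
#' @param min_carriers Carrier count below which the design is deemed sparse.
#' @param qx Optional precomputed `qr(covariates)`.
#' @export
mr_test <- function(trait, genotype, covariates, bootstrap = NULL,
                    B = 1000L, min_carriers = 20L, qx = NULL) {
  y <- as.numeric(trait)
  g <- as.numeric(genotype)
  X <- as.matrix(covariates)
  n <- length(y); p <- ncol(X)
  g_res <- qr.resid(if (is.null(qx)) qr(X) else qx, g)
  if (genotype_is_degenerate(sum(g_res^2), g))
    return(new_assoc_result("mr", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  XF <- cbind(X, genotype = g)
  fit <- lad_fit(y, XF)
  beta <- unname(fit$coefficients[p + 1L])
  df <- n - p - 1L
  flags <- character(0)
  sparse <- sum(g > 0) < min_carriers
  use_boot <- isTRUE(bootstrap) || (is.null(bootstrap) && sparse)
  se <- NA_real_
  if (!use_boot) {
    s <- lad_sparsity(fit$residuals)
    if (!is.finite(s) || s <= 0) {
      use_boot <- TRUE
    } else {
      XtXinv <- chol2inv(chol(crossprod(XF)))
      se <- sqrt(0.25 * s^2 * XtXinv[p + 1L, p + 1L])
    }
  }
  if (use_boot && !isFALSE(bootstrap)) {
    bb <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      bb[b] <- tryCatch(
        lad_fit(y[idx], XF[idx, , drop = FALSE])$coefficients[p + 1L],
        error = function(e) NA_real_)
    }
    # rank-deficient resamples (possible when carriers are very few) are dropped
    bb <- bb[is.finite(bb)]
    se <- if (length(bb) >= max(20L, B / 2)) stats::sd(bb) else NA_real_
    flags <- c(flags, "bootstrap")
  }
  if (!is.finite(se) || se <= 0)
    return(new_assoc_result("mr", statistic = 0, p_value = 1,
                            flags = c(flags, "degenerate_se")))
  tstat <- beta / se
  new_assoc_result("mr", statistic = tstat^2,
                   p_value = 2 * stats::pt(-abs(tstat), df),
                   beta_hat = beta, se = se,
                   converged = fit$converged, flags = flags)
}
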