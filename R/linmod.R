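#' @title Least-squares primitives and single-variant test statistics
#' @name linmod
#' @keywords internal
NULL

new_assoc_result <- function(method, statistic, p_value,
                             beta_hat = NA_real_, se = NA_real_,
                             iterations = 0L, converged = TRUE,
                             flags = character(0)) {
  structure(
    list(method = method, beta_hat = beta_hat, se = se,
         statistic = statistic, p_value = p_value,
         iterations = as.integer(iterations), converged = converged,
         flags = flags),
    class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Single-variant association test:", x$method, "\n")
  if (is.finite(x$beta_hat))
    cat(sprintf("  beta = %.6g (se %.6g)\n", x$beta_hat, x$se))
  cat(sprintf("  statistic = %.6g, p = %.6g\n", x$statistic, x$p_value))
  if (x$iterations > 0L || !x$converged)
    cat(sprintf("  iterations = %d, converged = %s\n",
                x$iterations, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

check_design <- function(X, what = "covariate") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("design matrix must be numeric")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    nm <- colnames(X)
    lab <- if (is.null(nm)) paste0("column ", bad) else nm[bad]
    stop("rank-deficient ", what, " design; collinear: ",
         paste(lab, collapse = ", "))
  }
  kap <- kappa(qr.R(qx), exact = FALSE)
  if (is.finite(kap) && kap > 1e8)
    warning("ill-conditioned ", what, " design (condition number ",
            format(kap, digits = 3), ")")
  qx
}

#' Fit the covariate-only null model by ordinary least squares
#'
#' Regresses the trait on the covariate design (which must contain the
#' intercept) and caches the QR factorization so that projections
#' \eqn{X(X^\top X)^{-1} X^\top v} can be formed without explicit inverses.
#'
#' @param trait Numeric trait vector \eqn{y}.
#' @param covariates Numeric design matrix \eqn{X} (n x p, full column rank,
#'   first column the intercept).
#' @return An object of class `null_model_fit`: coefficients, residuals,
#'   `residual_variance` \eqn{\hat\sigma^2 = \|\hat\varepsilon\|^2/(n-p)},
#'   and the QR handle.
#' @export
fit_null <- function(trait, covariates) {
  y <- as.numeric(trait)
  X <- as.matrix(covariates)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("trait and covariates must share length n")
  if (anyNA(y) || anyNA(X)) stop("missing values: complete cases required")
  if (n <= p) stop("need n > p observations")
  qx <- check_design(X)
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  s2 <- sum(res^2) / (n - p)
  flags <- character(0)
  if (s2 <= .Machine$double.eps * max(1, sum(y^2) / n))
    flags <- "degenerate_null"
  structure(
    list(coefficients = coef, residuals = res, residual_variance = s2,
         qr = qx, n = n, p = p, flags = flags),
    class = "null_model_fit")
}

# residualize a vector against the cached covariate design
project_out <- function(null_fit, v) qr.resid(null_fit$qr, as.numeric(v))

genotype_is_degenerate <- function(gIHg, g) {
  gIHg <= max(1e-10, 1e-10 * sum(g * g))
}

#' Covariate-adjusted score test for a single variant
#'
#' The rare-variant score test: with \eqn{H} the covariate hat matrix,
#' \eqn{U = g^\top\hat\varepsilon}, \eqn{V = \hat\sigma^2\, g^\top(I-H)g},
#' and \eqn{U^2/V} referred to \eqn{\chi^2_1}. For a single variant this is
#' the p-value the SKAT kernel test produces regardless of variant weight.
#'
#' @param null_fit A [fit_null()] object for the same samples.
#' @param genotype Additive dosage vector in `[0, 2]`.
#' @param covariates The design used in `null_fit` (accepted for interface
#'   symmetry; the cached factorization is used).
#' @return An `assoc_result`. Monomorphic or fully covariate-explained
#'   genotypes give `p_value = 1` with flag `"degenerate_genotype"`.
#' @export
score_test <- function(null_fit, genotype, covariates = NULL) {
  g <- as.numeric(genotype)
  if (length(g) != null_fit$n) stop("genotype length mismatch")
  g_res <- project_out(null_fit, g)
  gIHg <- sum(g_res^2)
  if (genotype_is_degenerate(gIHg, g))
    return(new_assoc_result("score", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  if ("degenerate_null" %in% null_fit$flags)
    return(new_assoc_result("score", statistic = 0, p_value = 1,
                            flags = "degenerate_null"))
  U <- sum(g * null_fit$residuals)
  V <- null_fit$residual_variance * gIHg
  stat <- U^2 / V
  new_assoc_result("score", statistic = stat,
                   p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   beta_hat = U / gIHg,
                   se = sqrt(null_fit$residual_variance / gIHg))
}

#' Wald test for the genotype coefficient in the joint linear model
#'
#' OLS of the trait on `[covariates, genotype]`; the squared t statistic for
#' the genotype coefficient is referred to \eqn{F(1, n-p-1)} (equivalently a
#' two-sided t test).
#'
#' @inheritParams score_test
#' @param trait Numeric trait vector.
#' @param covariates Covariate design matrix including the intercept.
#' @param qx Optional precomputed `qr(covariates)`.
#' @export
wald_test <- function(trait, genotype, covariates, qx = NULL) {
  y <- as.numeric(trait)
  X <- as.matrix(covariates)
  g <- as.numeric(genotype)
  n <- length(y); p <- ncol(X)
  nullq <- if (is.null(qx)) qr(X) else qx
  g_res <- qr.resid(nullq, g)
  if (genotype_is_degenerate(sum(g_res^2), g))
    return(new_assoc_result("wald", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  XF <- cbind(X, genotype = g)
  qf <- check_design(XF, "joint")
  cf <- qr.coef(qf, y)
  res <- qr.resid(qf, y)
  df <- n - p - 1L
  s2 <- sum(res^2) / df
  # var(beta_hat) = s2 / g'(I-H)g by Frisch-Waugh
  se <- sqrt(s2 / sum(g_res^2))
  beta <- unname(cf[p + 1L])
  stat <- (beta / se)^2
  new_assoc_result("wald", statistic = stat,
                   p_value = stats::pf(stat, 1, df, lower.tail = FALSE),
                   beta_hat = beta, se = se)
}

#' Partial F test comparing the covariate-only and joint models
#'
#' \eqn{F = (SSE_{reduced} - SSE_{full}) / (SSE_{full}/(n-p-1))} on
#' \eqn{(1, n-p-1)} df; numerically identical to the squared Wald t.
#'
#' @inheritParams wald_test
#' @export
partial_f_test <- function(trait, genotype, covariates) {
  y <- as.numeric(trait)
  X <- as.matrix(covariates)
  g <- as.numeric(genotype)
  n <- length(y); p <- ncol(X)
  nullq <- qr(X)
  if (genotype_is_degenerate(sum(qr.resid(nullq, g)^2), g))
    return(new_assoc_result("partial_f", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  sse_red <- sum(qr.resid(nullq, y)^2)
  qf <- check_design(cbind(X, genotype = g), "joint")
  sse_full <- sum(qr.resid(qf, y)^2)
  df <- n - p - 1L
  Fstat <- (sse_red - sse_full) / (sse_full / df)
  new_assoc_result("partial_f", statistic = Fstat,
                   p_value = stats::pf(Fstat, 1, df, lower.tail = FALSE))
}
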