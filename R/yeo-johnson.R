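#' Yeo-Johnson power transformation
#'
#' The four-branch family: for \eqn{y \ge 0},
#' \eqn{((y+1)^\lambda - 1)/\lambda} (or \eqn{\log(y+1)} at \eqn{\lambda=0});
#' for \eqn{y < 0}, \eqn{-((1-y)^{2-\lambda} - 1)/(2-\lambda)} (or
#' \eqn{-\log(1-y)} at \eqn{\lambda=2}). `yj_transform(y, 1)` is the identity.
#'
#' @param y Numeric vector.
#' @param lambda Transformation parameter.
#' @return Transformed vector.
#' @export
yj_transform <- function(y, lambda) {
  if (lambda == 1) return(as.numeric(y))  # exact identity branch
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(y[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((1 - y[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-y[!pos])
  }
  out
}

# Gaussian profile log-likelihood of lambda given a fixed design QR:
# -n/2 log(RSS/n) + (lambda - 1) * sum sign(y) log(1 + |y|)  (Jacobian)
yj_profile_loglik <- function(lambda, y, qx, log_jac_base) {
  psi <- yj_transform(y, lambda)
  rss <- sum(qr.resid(qx, psi)^2)
  if (!is.finite(rss) || rss <= 0) return(-Inf)
  n <- length(y)
  -n / 2 * log(rss / n) + (lambda - 1) * log_jac_base
}

#' Yeo-Johnson power-transformation regression test
#'
#' Estimates \eqn{\lambda} by profile maximum likelihood under the full model
#' `[covariates, genotype]` over \eqn{\lambda \in} `lambda_range`, transforms
#' the trait at \eqn{\hat\lambda}, and Wald-tests the genotype coefficient on
#' the transformed scale.
#'
#' @inheritParams wald_test
#' @param lambda_range Search interval for the profile likelihood.
#' @param null_model If `TRUE`, estimate lambda under the covariate-only
#'   model instead of the full model.
#' @param qx Optional precomputed `qr(covariates)`.
#' @return An `assoc_result`; the estimated lambda is attached as
#'   attribute `"lambda"`.
#' @export
yjpt_test <- function(trait, genotype, covariates, lambda_range = c(-5, 5),
                      null_model = FALSE, qx = NULL) {
  y <- as.numeric(trait)
  g <- as.numeric(genotype)
  X <- as.matrix(covariates)
  if (is.null(qx)) qx_cov <- qr(X) else qx_cov <- qx
  g_res <- qr.resid(qx_cov, g)
  if (genotype_is_degenerate(sum(g_res^2), g))
    return(new_assoc_result("yjpt", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  design <- if (null_model) X else cbind(X, genotype = g)
  qd <- qr(design)
  log_jac_base <- sum(sign(y) * log1p(abs(y)))
  opt <- stats::optimize(yj_profile_loglik, interval = lambda_range,
                         maximum = TRUE, tol = 1e-5,
                         y = y, qx = qd, log_jac_base = log_jac_base)
  if (!is.finite(opt$objective))
    stop("non-finite Yeo-Johnson profile likelihood; lambda search at ",
         format(opt$maximum), ", trait range [",
         paste(format(range(y)), collapse = ", "), "]")
  lambda <- opt$maximum
  res <- wald_test(yj_transform(y, lambda), g, X, qx = qx_cov)
  res$method <- "yjpt"
  attr(res, "lambda") <- lambda
  res
}
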