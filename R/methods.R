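#' Bundle one variant's analysis inputs
#'
#' @param trait Numeric trait vector \eqn{y}.
#' @param covariates Design matrix with the intercept as first column; a
#'   bare intercept column is added when `NULL`.
#' @param genotype Additive dosage vector with values in `[0, 2]`.
#' @return A `sample_data` list (trait, covariates, genotype, n).
#' @export
sample_data <- function(trait, genotype, covariates = NULL) {
  y <- as.numeric(trait)
  n <- length(y)
  g <- as.numeric(genotype)
  if (is.null(covariates)) covariates <- matrix(1, n, 1,
                                                dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(covariates)
  if (length(g) != n || nrow(X) != n)
    stop("trait, genotype and covariates must share length n")
  if (anyNA(y) || anyNA(g) || anyNA(X))
    stop("missing values: complete cases required")
  if (any(g < 0 | g > 2)) stop("genotype dosages must lie in [0, 2]")
  if (any(abs(X[, 1] - 1) > 0))
    stop("first covariate column must be the intercept")
  structure(list(trait = y, covariates = X, genotype = g, n = n),
            class = "sample_data")
}

# null_model_fit from a precomputed covariate QR (shared across methods)
null_from_qr <- function(qx, y, p) {
  res <- qr.resid(qx, y)
  n <- length(y)
  s2 <- sum(res^2) / (n - p)
  flags <- if (s2 <= .Machine$double.eps * max(1, sum(y^2) / n))
    "degenerate_null" else character(0)
  structure(list(coefficients = qr.coef(qx, y), residuals = res,
                 residual_variance = s2, qr = qx, n = n, p = p,
                 flags = flags),
            class = "null_model_fit")
}

relabel <- function(res, label) { res$method <- label; res }

# covariate QR, reusing one attached by the caller (the simulation engine
# attaches it so the methods sharing a dataset factorize X only once)
covar_qr <- function(data) if (!is.null(data$qx)) data$qx else qr(data$covariates)

#' Partly adjusted two-stage INT test
#'
#' Stage 1 residuals of the trait on the covariates are rank-normalized, then
#' tested against the genotype with only the intercept re-adjusted — the
#' historically common shortcut whose type I error deflates under
#' genotype-covariate confounding.
#'
#' @param data A [sample_data()] object.
#' @param ... Passed to the underlying primitives.
#' @return An `assoc_result`.
#' @export
pts_int <- function(data, ...) {
  qx <- covar_qr(data)
  r <- rank_inverse_normal(qr.resid(qx, data$trait))
  icpt <- matrix(1, data$n, 1)
  nf <- null_from_qr(qr(icpt), r, 1L)
  relabel(score_test(nf, data$genotype), "pts-int")
}

#' Fully adjusted two-stage INT test
#'
#' Rank-normalized stage-1 residuals are tested against the genotype with the
#' same covariates re-adjusted in the second stage (the fully adjusted
#' two-stage procedure).
#'
#' @inheritParams pts_int
#' @export
ts_int <- function(data, ...) {
  qx <- covar_qr(data)
  r <- rank_inverse_normal(qr.resid(qx, data$trait))
  nf <- null_from_qr(qx, r, ncol(data$covariates))
  relabel(score_test(nf, data$genotype), "ts-int")
}

#' Direct INT test
#'
#' The trait itself is rank-normalized and regressed jointly on the genotype
#' and covariates; the genotype coefficient is Wald-tested.
#'
#' @inheritParams pts_int
#' @export
d_int <- function(data, ...) {
  z <- rank_inverse_normal(data$trait)
  relabel(wald_test(z, data$genotype, data$covariates, qx = covar_qr(data)),
          "d-int")
}

#' Indirect INT test
#'
#' Stage-1 residuals are rank-normalized and the genotype is residualized on
#' the covariates; the transformed residuals are score-tested against the
#' genotype residuals (intercept-only null).
#'
#' @inheritParams pts_int
#' @export
i_int <- function(data, ...) {
  qx <- covar_qr(data)
  r <- rank_inverse_normal(qr.resid(qx, data$trait))
  e_g <- qr.resid(qx, data$genotype)
  if (genotype_is_degenerate(sum(e_g^2), data$genotype))
    return(new_assoc_result("i-int", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  icpt <- matrix(1, data$n, 1)
  nf <- null_from_qr(qr(icpt), r, 1L)
  relabel(score_test(nf, e_g), "i-int")
}

#' Omnibus INT test
#'
#' Combines the direct and indirect INT p-values with the Cauchy (ACAT)
#' combination under equal weights. If one sub-test is degenerate the other's
#' p-value is reported with a fallback flag.
#'
#' @inheritParams pts_int
#' @export
o_int <- function(data, ...) {
  rd <- d_int(data)
  ri <- i_int(data)
  deg_d <- "degenerate_genotype" %in% rd$flags
  deg_i <- "degenerate_genotype" %in% ri$flags
  if (deg_d && deg_i)
    return(new_assoc_result("o-int", statistic = 0, p_value = 1,
                            flags = "degenerate_genotype"))
  if (deg_d)
    return(new_assoc_result("o-int", statistic = ri$statistic,
                            p_value = ri$p_value, flags = "fallback_i_int"))
  if (deg_i)
    return(new_assoc_result("o-int", statistic = rd$statistic,
                            p_value = rd$p_value, flags = "fallback_d_int"))
  p <- cauchy_combine(c(rd$p_value, ri$p_value))
  new_assoc_result("o-int", statistic = tan((0.5 - p) * pi), p_value = p)
}

#' Fully adjusted full-stage INT test
#'
#' The iterative procedure: (1) residualize the trait on the covariates and
#' rank-normalize; (2) regress the transformed residuals on the covariates
#' and screen the covariate p-values at `screen_alpha`; (3) while any
#' screened p-value is below the threshold, re-residualize, re-transform and
#' re-screen, stopping also when the covariate coefficients change by less
#' than `coef_tolerance` (sup-norm) between successive transforms or after
#' `max_iterations`; (4) score-test the final transformed residuals against
#' the genotype adjusting the covariates. When the first screen already
#' passes the result is identical to [ts_int()] with `iterations = 0`.
#'
#' @inheritParams pts_int
#' @param screen_alpha Covariate-effect screening level (default 0.05).
#' @param coef_tolerance Sup-norm stopping tolerance on successive covariate
#'   coefficient vectors (default 1e-6).
#' @param max_iterations Hard iteration cap; exceeding it sets
#'   `converged = FALSE`.
#' @param include_intercept_in_screen Screen the intercept's p-value too
#'   (default `FALSE`: transformed residuals are symmetric about zero, so the
#'   intercept p-value is uninformative).
#' @export
fs_int <- function(data, screen_alpha = 0.05, coef_tolerance = 1e-6,
                   max_iterations = 100L, include_intercept_in_screen = FALSE,
                   ...) {
  if (max_iterations < 1L) stop("max_iterations must be at least 1")
  X <- data$covariates
  n <- data$n; p <- ncol(X)
  qx <- covar_qr(data)
  # (X'X)^{-1} diagonal once, honouring any pivoting in the factorization
  R <- qr.R(qx)
  XtXinv <- chol2inv(R)
  unpiv <- order(qx$pivot[seq_len(p)])
  d_inv <- diag(XtXinv)[unpiv]
  screened <- if (include_intercept_in_screen || p == 1L) seq_len(p) else 2:p
  covar_screen <- function(r) {
    cf <- qr.coef(qx, r)
    res <- qr.resid(qx, r)
    s2 <- sum(res^2) / (n - p)
    se <- sqrt(s2 * d_inv)
    pv <- 2 * stats::pt(-abs(cf / se), n - p)
    list(coef = cf, resid = res, p = pv)
  }

  r <- rank_inverse_normal(qr.resid(qx, data$trait))
  iter <- 0L
  converged <- TRUE
  cur <- covar_screen(r)
  while (any(cur$p[screened] < screen_alpha)) {
    if (iter >= max_iterations) {
      converged <- FALSE
      warning("fs_int: iteration cap reached without convergence")
      break
    }
    alpha_tilde <- cur$coef
    r <- rank_inverse_normal(cur$resid)
    iter <- iter + 1L
    cur <- covar_screen(r)
    if (max(abs((alpha_tilde - cur$coef)[screened])) < coef_tolerance)
      break
  }
  nf <- null_from_qr(qx, r, p)
  out <- relabel(score_test(nf, data$genotype), "fs-int")
  out$iterations <- iter
  out$converged <- converged && out$converged
  out
}

#' Plain covariate-adjusted score test (single-variant SKAT)
#'
#' @inheritParams pts_int
#' @export
skat_score <- function(data, ...) {
  qx <- covar_qr(data)
  nf <- null_from_qr(qx, data$trait, ncol(data$covariates))
  relabel(score_test(nf, data$genotype), "skat-score")
}

#' Available association methods
#'
#' @return Named list mapping method keys to functions of
#'   `(data, ...)`.
#' @export
assoc_methods <- function() {
  list(
    "mr" = function(data, ...) mr_test(data$trait, data$genotype,
                                       data$covariates,
                                       qx = covar_qr(data), ...),
    "yjpt" = function(data, ...) yjpt_test(data$trait, data$genotype,
                                           data$covariates,
                                           qx = covar_qr(data), ...),
    "skat-score" = skat_score,
    "d-int" = d_int,
    "i-int" = i_int,
    "o-int" = o_int,
    "pts-int" = pts_int,
    "ts-int" = ts_int,
    "fs-int" = fs_int)
}

#' Run one association method by key
#'
#' @param data A [sample_data()] object.
#' @param method One of `names(assoc_methods())`.
#' @param ... Method-specific options.
#' @export
assoc_test <- function(data, method = "fs-int", ...) {
  funs <- assoc_methods()
  if (!method %in% names(funs))
    stop("unknown method '", method, "'; available: ",
         paste(names(funs), collapse = ", "))
  funs[[method]](data, ...)
}
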