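#' Single-variant association tests for a quantitative trait
#'
#' The main fitting interface. The formula names the trait and covariates
#' (`trait ~ age + sex`); factors are expanded by [stats::model.matrix()]
#' with treatment contrasts and the intercept is always included. Each column
#' of `genotype` is tested with the requested method(s).
#'
#' @param formula Model formula `trait ~ covariates` (use `trait ~ 1` for an
#'   unadjusted analysis).
#' @param data Data frame holding the trait and covariates.
#' @param genotype Numeric dosage vector or samples-by-variants matrix with
#'   values in `[0, 2]`. Missing dosages are handled per variant by
#'   complete-case analysis.
#' @param method Method key (see [assoc_methods()]) or `"all"`.
#' @param ... Method-specific options (e.g. `screen_alpha` for `"fs-int"`).
#' @return An object of class `int_assoc` with `print`, `summary` and
#'   `coef` methods; `$results` is the per-(variant, method) table.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rnorm(200), age = rnorm(200))
#' g <- rbinom(200, 2, 0.3)
#' fit <- int_assoc(y ~ age, d, genotype = g, method = "fs-int")
#' fit
#' @export
int_assoc <- function(formula, data, genotype, method = "fs-int", ...) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!"(Intercept)" %in% colnames(X))
    stop("the covariate design must include an intercept")
  G <- as.matrix(genotype)
  if (is.null(colnames(G)))
    colnames(G) <- if (ncol(G) == 1L) "g" else paste0("variant", seq_len(ncol(G)))
  if (nrow(G) != length(y))
    stop("genotype rows must match the number of samples")
  keys <- if (identical(method, "all")) names(assoc_methods()) else method
  bad <- setdiff(keys, names(assoc_methods()))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))

  rows <- vector("list", ncol(G) * length(keys))
  k <- 0L
  for (j in seq_len(ncol(G))) {
    gj <- G[, j]
    ok <- stats::complete.cases(y, X, gj)
    n_used <- sum(ok)
    for (key in keys) {
      k <- k + 1L
      res <- tryCatch({
        sd_j <- sample_data(y[ok], gj[ok], X[ok, , drop = FALSE])
        assoc_test(sd_j, key, ...)
      }, error = function(e)
        new_assoc_result(key, statistic = NA_real_, p_value = NA_real_,
                         converged = FALSE,
                         flags = paste0("error: ", conditionMessage(e))))
      rows[[k]] <- data.frame(
        variant = colnames(G)[j], method = res$method, n_used = n_used,
        beta_hat = res$beta_hat, se = res$se, statistic = res$statistic,
        p_value = res$p_value, iterations = res$iterations,
        converged = res$converged,
        flags = paste(res$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(call = cl, methods = keys, n = length(y),
                 results = do.call(rbind, rows)),
            class = "int_assoc")
}

#' @export
print.int_assoc <- function(x, ...) {
  cat("Quantitative-trait association tests\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d sample(s), %d variant(s), method(s): %s\n\n", x$n,
              length(unique(x$results$variant)),
              paste(x$methods, collapse = ", ")))
  df <- x$results
  df$p_value <- format(df$p_value, digits = 4)
  print(df[, c("variant", "method", "n_used", "beta_hat", "p_value",
               "iterations", "converged")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.int_assoc <- function(object, alpha = 0.05, ...) {
  df <- object$results
  cat("Association summary (", nrow(df), " tests)\n", sep = "")
  sig <- df[!is.na(df$p_value) & df$p_value < alpha, ]
  if (nrow(sig)) {
    cat("Tests with p <", alpha, ":\n")
    print(sig[, c("variant", "method", "beta_hat", "p_value")],
          row.names = FALSE)
  } else cat("No test below p <", alpha, "\n")
  flagged <- df[nzchar(df$flags), ]
  if (nrow(flagged)) {
    cat("Flagged tests:\n")
    print(flagged[, c("variant", "method", "flags")], row.names = FALSE)
  }
  invisible(df)
}

#' @export
coef.int_assoc <- function(object, ...) {
  df <- object$results
  stats::setNames(df$beta_hat, paste(df$variant, df$method, sep = ":"))
}
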