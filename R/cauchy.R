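#' Cauchy (ACAT) combination of p-values
#'
#' Transforms each p-value to a standard Cauchy variate
#' \eqn{\tan\{(1/2 - p)\pi\}}, averages with the given weights, and maps the
#' average back: \eqn{p = 1/2 - \arctan(T)/\pi}. Exact under arbitrary
#' dependence when each component is uniform under the null.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param weights Non-negative weights, normalized internally (default equal).
#' @return Combined p-value.
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  # for tiny p, tan((1/2 - p)*pi) ~ 1/(p*pi): avoids overflow of the tangent
  tiny <- p < 1e-15
  t_vals <- numeric(length(p))
  t_vals[!tiny] <- tan((0.5 - p[!tiny]) * pi)
  t_vals[tiny] <- 1 / (p[tiny] * pi)
  T_stat <- sum(w * t_vals)
  if (T_stat > 1e15) return(1 / (T_stat * pi))
  0.5 - atan(T_stat) / pi
}
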