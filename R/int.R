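#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to standard-normal quantiles of its (offset) ranks:
#' \eqn{\Phi^{-1}\{(\mathrm{rank}(v_i) - c)/n\}}. With the conventional offset
#' \eqn{c = 1/2} the probabilities lie in \eqn{[0.5/n, 1 - 0.5/n]}, so the
#' output is always finite. The transform preserves ranks exactly; with the
#' default average tie rule, tied inputs map to identical outputs.
#'
#' @param x Numeric vector, length >= 1, all values finite.
#' @param offset Rank offset \eqn{c \in (0, 1/2]}. The degenerate value
#'   \eqn{c = 0} would send the largest rank to \eqn{\Phi^{-1}(1) = \infty}
#'   and is rejected.
#' @param ties How tied values are ranked: `"average"` (default), `"min"`,
#'   `"max"` or `"random"`.
#' @param denominator Either `"n"` (the form used here, probabilities
#'   \eqn{(r - c)/n}) or `"blom"` for the \eqn{n - 2c + 1} variant offered for
#'   comparison only.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' rank_inverse_normal(c(3, 1, 2, 5, 4))
#' @export
rank_inverse_normal <- function(x, offset = 0.5,
                                ties = c("average", "min", "max", "random"),
                                denominator = c("n", "blom")) {
  ties <- match.arg(ties)
  denominator <- match.arg(denominator)
  if (length(x) == 0L) stop("empty vector")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("input must be finite numeric")
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0 || offset > 0.5)
    stop("offset must be a single value in [0, 1/2]")
  if (offset == 0)
    stop("degenerate probability 1: offset c = 0 maps the largest rank to +Inf")
  n <- length(x)
  r <- rank(x, ties.method = ties)
  p <- if (denominator == "n") (r - offset) / n else
    (r - offset) / (n - 2 * offset + 1)
  stats::qnorm(p)
}
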