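#' Rank-based inverse normal transformation
#'
#' Maps each value to the standard-normal quantile of its (tie-averaged)
#' rank: element i becomes \eqn{\Phi^{-1}((r_i - 0.5)/n)} under the default
#' offset, or \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))} under the Blom offset.
#' The result is a monotone function of the input ranks, so the transform is
#' invariant to any strictly increasing transformation of the input and
#' idempotent up to ranks.
#'
#' Routinely applied to expression phenotypes before eQTL analysis; note
#' that because it is non-linear it changes the scale on which interaction
#' effects are defined, and can create or remove statistical interactions
#' when the modeled effects are large.
#'
#' @param values numeric vector (length >= 2, at least two distinct values).
#' @param offset quantile offset rule: \code{"half"} (default) or
#'   \code{"blom"}.
#' @return Numeric vector of normal scores (sample mean approximately 0,
#'   variance approximately 1 for large tie-free input).
#' @examples
#' rankInverseNormal(c(3, 1, 2))
#' @export
rankInverseNormal <- function(values, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  if (length(values) < 2L)
    stop("'values' must have length >= 2")
  if (anyNA(values))
    stop("'values' must not contain NA")
  if (length(unique(values)) < 2L)
    stop("constant input: ranks are undefined for a degenerate vector")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  q <- switch(offset,
              half = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4))
  qnorm(q)
}
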