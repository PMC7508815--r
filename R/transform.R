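#' Map unconstrained parameter values to their constrained scale
#'
#' Hierarchical estimation works on an unconstrained scale; constrained
#' parameter values are obtained through the standard normal cumulative
#' distribution function \eqn{\Phi}: unit-interval parameters map as
#' \eqn{\Phi(x) \in (0,1)} and unbounded-above parameters (temperature,
#' attentional focus, decision consistency) as \eqn{5\,\Phi(x) \in (0,5)}.
#' The transform is strictly increasing; \code{wcst_unconstrain} is its
#' inverse.
#'
#' @param x numeric vector of unconstrained values.
#' @param p numeric vector of constrained values.
#' @param kind \code{"unit"} or \code{"five"}.
#' @return numeric vector of the same length.
#' @examples
#' wcst_constrain(0, "unit")   # 0.5
#' wcst_constrain(0, "five")   # 2.5
#' wcst_unconstrain(0.975, "unit")
#' @export
wcst_constrain <- function(x, kind = c("unit", "five")) {
  kind <- match.arg(kind)
  if (kind == "unit") pnorm(x) else 5 * pnorm(x)
}

#' @rdname wcst_constrain
#' @export
wcst_unconstrain <- function(p, kind = c("unit", "five")) {
  kind <- match.arg(kind)
  if (kind == "five") p <- p / 5
  qnorm(p)
}

## vectorized over a model's canonical parameter order
constrain_vector <- function(x, model) {
  kinds <- wcst_param_kinds(model)
  out <- ifelse(kinds == "five", 5 * pnorm(x), pnorm(x))
  names(out) <- names(kinds)
  out
}

unconstrain_vector <- function(p, model) {
  kinds <- wcst_param_kinds(model)
  p <- as_param_vector(p, model)
  out <- ifelse(kinds == "five", qnorm(p / 5), qnorm(p))
  names(out) <- names(kinds)
  out
}
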