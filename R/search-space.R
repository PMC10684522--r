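#' Box-constrained search space
#'
#' Describes the rectangular domain a metaheuristic searches: per-dimension
#' lower and upper bounds.
#'
#' @param lower Numeric vector of lower bounds.
#' @param upper Numeric vector of upper bounds, same length as `lower`.
#'
#' @return An object of class `search_space` with fields `lower`, `upper`
#'   and `dim`.
#' @examples
#' sp <- search_space(rep(-10, 5), rep(10, 5))
#' sp$dim
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length")
  }
  if (length(lower) < 1L) stop("search space must have at least one dimension")
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound")
  }
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "search_space")
}

#' Clamp a position to the search-space box
#'
#' Elementwise `min(max(pos, lower), upper)`; idempotent boundary handling
#' used by every optimizer in the package.
#'
#' @param pos Numeric position vector.
#' @param space A [search_space()].
#' @return The clamped position.
#' @examples
#' clamp_to_bounds(c(11, -11), search_space(c(-10, -10), c(10, 10)))
#' @export
clamp_to_bounds <- function(pos, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(pos) != space$dim) stop("position dimension does not match space")
  pmin(pmax(pos, space$lower), space$upper)
}
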