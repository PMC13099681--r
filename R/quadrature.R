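#' Quadrature grid for the standard-normal latent trait
#'
#' Builds the discrete node/weight approximation to the standard-normal
#' latent density used throughout marginal maximum-likelihood estimation:
#' `k` equally spaced nodes on `[-bound, bound]` with weights proportional
#' to the standard-normal density at each node, renormalized to sum to one
#' (classic Bock-Aitkin practice).
#'
#' @param k Number of quadrature nodes (default 49, at least 3).
#' @param bound Half-width of the node range in latent-trait standard
#'   deviations (default 6).
#' @return A tibble with columns `node` (strictly increasing) and `weight`
#'   (non-negative, summing to 1), of class `quadrature_grid`.
#' @examples
#' quadrature_grid(k = 5, bound = 2)
#' @export
quadrature_grid <- function(k = 49, bound = 6) {
  if (length(k) != 1L || !is.finite(k) || k < 3 || k != round(k)) {
    abort("`k` must be a single integer >= 3.")
  }
  if (length(bound) != 1L || !is.finite(bound) || bound <= 0) {
    abort("`bound` must be a single positive number.")
  }
  nodes <- seq(-bound, bound, length.out = k)
  w <- dnorm(nodes)
  grid <- tibble::tibble(node = nodes, weight = w / sum(w))
  class(grid) <- c("quadrature_grid", class(grid))
  grid
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature_grid: %d nodes on [%.3g, %.3g]>\n",
              nrow(x), min(x$node), max(x$node)))
  NextMethod()
}

as_grid <- function(grid) {
  if (is.null(grid)) grid <- quadrature_grid()
  stopifnot(is.data.frame(grid), all(c("node", "weight") %in% names(grid)))
  list(nodes = as.numeric(grid$node), weights = as.numeric(grid$weight))
}
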