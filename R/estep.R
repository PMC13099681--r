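#' Posterior over quadrature nodes for one response pattern
#'
#' Computes `g(eta_k | u, phi)`, the discrete posterior of the latent trait
#' given a single (possibly partially missing) response pattern:
#' proportional to `w_k * prod_{i observed} P_i(eta_k)^u_i Q_i(eta_k)^(1-u_i)`,
#' normalized over nodes.  All likelihood work is done on the log scale with
#' log-sum-exp stabilization, so long patterns do not underflow.
#'
#' @param pattern Numeric vector of 0/1/`NA` responses, one per item.
#' @param params Item parameter table (columns `a`, `c`).
#' @param grid Quadrature grid from [quadrature_grid()] (default 49 nodes on
#'   `[-6, 6]`).
#' @return Tibble with columns `node`, `weight` (prior) and `posterior`
#'   (non-negative, summing to 1).
#' @examples
#' pattern_posterior(c(1, 0), item_params(a = c(1, 1), c = c(0, 0)))
#' @export
pattern_posterior <- function(pattern, params, grid = quadrature_grid()) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  if (length(pattern) != length(p$a)) {
    abort("`pattern` length must equal the number of items.")
  }
  U <- matrix(pattern, nrow = 1)
  pd <- new_pattern_data(U, f = 1, n_persons = 1)
  res <- estep_cpp(pd$U, pd$O, pd$f, p$a, p$c, g$nodes, g$weights,
                   keep_posterior = TRUE)
  if (!is.finite(res$pattern_loglik[1])) {
    abort("Pattern likelihood underflowed at every quadrature node.")
  }
  tibble::tibble(node = g$nodes, weight = g$weights,
                 posterior = as.numeric(res$posterior[1, ]))
}

#' Marginal log-likelihood of 2PL item parameters
#'
#' The observed-data log-likelihood, summed over response patterns with the
#' latent trait integrated out by quadrature:
#' `sum_r f_r log sum_k w_k prod_{i observed} P_i^{u_ir} Q_i^{1-u_ir}`.
#'
#' @param data Response matrix/data frame or a `pattern_data` object.
#' @param params Item parameter table (columns `a`, `c`).
#' @param grid Quadrature grid.
#' @return A single number.
#' @export
marginal_loglik <- function(data, params, grid = quadrature_grid()) {
  pd <- if (inherits(data, "pattern_data")) data else compress_patterns(data)
  if (nrow(pd$U) == 0) abort("Empty pattern data.")
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  estep_cpp(pd$U, pd$O, pd$f, p$a, p$c, g$nodes, g$weights)$loglik
}

#' Expected response counts (E-step)
#'
#' One Bock-Aitkin E-step: for every item i and node k, the expected counts
#' of 1- and 0-responses under the current posterior,
#' `r1[i,k] = sum_r f_r g_kr u_ir` and `r0[i,k] = sum_r f_r g_kr (1-u_ir)`,
#' with sums restricted to patterns where item i is observed.  Applied to a
#' subset's `pattern_data` this is exactly the partial E-step; the
#' computation is identical, only the patterns differ.
#'
#' @inheritParams marginal_loglik
#' @return List with `r1`, `r0` (items x nodes matrices), `loglik` (the
#'   marginal log-likelihood, a free byproduct of the per-pattern
#'   normalizers) and `n_tilde = r1 + r0`.
#' @export
e_step <- function(data, params, grid = quadrature_grid()) {
  pd <- if (inherits(data, "pattern_data")) data else compress_patterns(data)
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  res <- estep_cpp(pd$U, pd$O, pd$f, p$a, p$c, g$nodes, g$weights)
  list(r1 = res$r1, r0 = res$r0, n_tilde = res$r1 + res$r0,
       loglik = res$loglik)
}

# fast path used by the engines: counts from an enum-encoded frequency
# vector (fully observed, small item count)
e_step_enum <- function(f_enum, a, c, g) {
  res <- estep_enum_cpp(f_enum, a, c, g$nodes, g$weights)
  n <- matrix(res$nk, nrow = length(a), ncol = length(g$nodes), byrow = TRUE)
  list(r1 = res$r1, r0 = n - res$r1, n_tilde = n, loglik = res$loglik)
}
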