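# Q-function machinery: the expected complete-data log-likelihood
#   Q_i = sum_k r1[i,k] log P_i(eta_k) + r0[i,k] log Q_i(eta_k)
# and its analytic gradient / Hessian in (a_i, c_i).  All internals are
# vectorized across items; the exported wrappers expose per-item views.

logit_mat <- function(a, c, nodes) {
  Z <- outer(nodes, a)
  Z + rep(c, each = length(nodes))    # K x I
}

prob_mat <- function(a, c, nodes) plogis(logit_mat(a, c, nodes))

q_value_all <- function(counts, a, c, nodes) {
  Z <- logit_mat(a, c, nodes)
  rowSums(counts$r1 * t(plogis(Z, log.p = TRUE)) +
            counts$r0 * t(plogis(Z, lower.tail = FALSE, log.p = TRUE)))
}

q_gradient_all <- function(counts, a, c, nodes, P = NULL) {
  if (is.null(P)) P <- prob_mat(a, c, nodes)
  D <- counts$r1 - counts$n_tilde * t(P)        # I x K
  cbind(a = as.numeric(D %*% nodes), c = rowSums(D))
}

q_hessian_all <- function(counts, a, c, nodes, P = NULL) {
  if (is.null(P)) P <- prob_mat(a, c, nodes)
  W <- counts$n_tilde * t(P * (1 - P))          # I x K
  list(aa = -as.numeric(W %*% nodes^2),
       cc = -rowSums(W),
       ac = -as.numeric(W %*% nodes))
}

#' Q-function value, gradient and Hessian for one item
#'
#' The M-step objective is the expected complete-data log-likelihood built
#' from E-step counts.  `q_value()` evaluates it, `q_gradient()` returns
#' `(dQ/da_i, dQ/dc_i) = (sum_k [r1 - n P] eta_k, sum_k [r1 - n P])` and
#' `q_hessian()` the symmetric, negative semidefinite 2x2 matrix with
#' entries `-sum_k n P Q eta_k^2`, `-sum_k n P Q` and `-sum_k n P Q eta_k`.
#'
#' @param counts E-step output from [e_step()] (`r1`, `r0`, `n_tilde`).
#' @param params Item parameter table at which to evaluate (columns `a`, `c`).
#' @param grid Quadrature grid.
#' @param item Item index (1-based).
#' @return `q_value()`: scalar; `q_gradient()`: named length-2 vector;
#'   `q_hessian()`: 2x2 matrix.
#' @export
q_gradient <- function(counts, params, grid = quadrature_grid(), item = 1) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  gr <- q_gradient_all(counts, p$a, p$c, g$nodes)[item, ]
  setNames(as.numeric(gr), c("a", "c"))
}

#' @rdname q_gradient
#' @export
q_hessian <- function(counts, params, grid = quadrature_grid(), item = 1) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  h <- q_hessian_all(counts, p$a, p$c, g$nodes)
  matrix(c(h$aa[item], h$ac[item], h$ac[item], h$cc[item]), 2, 2,
         dimnames = list(c("a", "c"), c("a", "c")))
}

#' @rdname q_gradient
#' @export
q_value <- function(counts, params, grid = quadrature_grid(), item = 1) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  q_value_all(counts, p$a, p$c, g$nodes)[item]
}

# one Newton direction H^{-1} grad per item, solved in closed form;
# returns NA rows where the Hessian is (numerically) singular
newton_direction <- function(gr, h) {
  det <- h$aa * h$cc - h$ac^2
  ok <- is.finite(det) & abs(det) > 1e-300
  da <- dc <- rep(NA_real_, length(det))
  da[ok] <- (h$cc[ok] * gr[ok, 1] - h$ac[ok] * gr[ok, 2]) / det[ok]
  dc[ok] <- (h$aa[ok] * gr[ok, 2] - h$ac[ok] * gr[ok, 1]) / det[ok]
  cbind(da, dc)
}

#' Exact M-step: per-item Newton maximization of the Q-function
#'
#' Iterates full Newton ascent steps (with step-halving whenever the
#' Q-function would decrease) independently for every item until the
#' gradient sup-norm falls below `tol` or `max_iter` inner iterations.
#' Because each accepted step improves Q, the surrounding EM iteration
#' inherits the generalized-EM monotonicity guarantee.
#'
#' @param counts E-step counts ([e_step()]).
#' @param start Item parameter table of starting values.
#' @param grid Quadrature grid.
#' @param tol Gradient sup-norm tolerance (default 1e-10).
#' @param max_iter Inner iteration cap (default 50).
#' @return Item parameter tibble of the maximizing values.
#' @export
m_step_full <- function(counts, start, grid = quadrature_grid(),
                        tol = 1e-10, max_iter = 50) {
  p <- as_param_vectors(start)
  g <- as_grid(grid)
  res <- m_step_newton(counts, p$a, p$c, g, tol = tol, max_iter = max_iter)
  item_params(res$a, res$c, item = p$item)
}

# vector-based Newton M-step shared by the EM engines
m_step_newton <- function(counts, a, c, g, tol = 1e-10, max_iter = 50) {
  qv <- q_value_all(counts, a, c, g$nodes)
  active <- TRUE
  for (it in seq_len(max_iter)) {
    gr <- q_gradient_all(counts, a, c, g$nodes)
    active <- pmax(abs(gr[, 1]), abs(gr[, 2])) >= tol
    if (!any(active)) break
    h <- q_hessian_all(counts, a, c, g$nodes)
    dir <- newton_direction(gr, h)
    dir[!active | !is.finite(dir[, 1]), ] <- 0
    step <- rep(1, length(a))
    for (halving in 1:30) {
      a_new <- a - step * dir[, 1]
      c_new <- c - step * dir[, 2]
      qv_new <- q_value_all(counts, a_new, c_new, g$nodes)
      worse <- active & (qv_new < qv - 1e-12 * abs(qv))
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    a <- a_new; c <- c_new; qv <- qv_new
  }
  if (any(active)) {
    gr <- q_gradient_all(counts, a, c, g$nodes)
    left <- which(pmax(abs(gr[, 1]), abs(gr[, 2])) >= tol)
    if (length(left) > 0) {
      warn(sprintf("M-step did not converge for item(s): %s",
                   paste(left, collapse = ", ")))
    }
  }
  list(a = a, c = c)
}

#' Damped Newton M-update (Stage-2 modified M-step)
#'
#' A single generalized-M-step update per item: one Newton ascent step of
#' relative length `gamma` on the Q-function built from (partial) E-step
#' counts.  With the Hessian of the Q-function being negative definite, the
#' ascent update is `phi - gamma * H^{-1} grad`.  Items whose 2x2 Hessian is
#' numerically singular are left unchanged for that update (with a warning).
#'
#' @param params Current item parameters (the working values).
#' @param counts (Partial) E-step counts.
#' @param grid Quadrature grid.
#' @param gamma Fixed step size in (0, 1] (default 0.5).
#' @return Updated item parameter tibble.
#' @export
modified_m_step <- function(params, counts, grid = quadrature_grid(),
                            gamma = 0.5) {
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  gr <- q_gradient_all(counts, p$a, p$c, g$nodes)
  h <- q_hessian_all(counts, p$a, p$c, g$nodes)
  dir <- newton_direction(gr, h)
  bad <- !is.finite(dir[, 1])
  if (any(bad)) {
    warn(sprintf("Singular Hessian; skipping update for item(s): %s",
                 paste(which(bad), collapse = ", ")))
    dir[bad, ] <- 0
  }
  item_params(p$a - gamma * dir[, 1], p$c - gamma * dir[, 2], item = p$item)
}
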