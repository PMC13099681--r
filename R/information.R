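param_labels <- function(n_items) {
  as.vector(rbind(paste0("a_", seq_len(n_items)),
                  paste0("c_", seq_len(n_items))))
}

#' Marginal score vector of one response pattern
#'
#' Gradient of the log marginal likelihood of a single pattern with respect
#' to all item parameters, ordered `(a_1, c_1, ..., a_I, c_I)`:
#' `d l_r / d a_i = sum_k g_kr [u_ir - P_i(eta_k)] eta_k` and
#' `d l_r / d c_i = sum_k g_kr [u_ir - P_i(eta_k)]`, where `g_kr` is the
#' pattern's posterior over quadrature nodes.  Entries for unobserved items
#' are zero.
#'
#' @param pattern Numeric 0/1/`NA` vector, one entry per item.
#' @param params Item parameter table (columns `a`, `c`).
#' @param grid Quadrature grid.
#' @return Named numeric vector of length `2 * I`.
#' @export
marginal_score <- function(pattern, params, grid = quadrature_grid()) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  pd <- new_pattern_data(matrix(pattern, nrow = 1), f = 1, n_persons = 1)
  res <- estep_cpp(pd$U, pd$O, pd$f, p$a, p$c, g$nodes, g$weights,
                   scores = TRUE)
  setNames(as.numeric(res$scores[1, ]), param_labels(length(p$a)))
}

# score matrix (patterns x 2I) and frequencies for arbitrary pattern data
score_matrix <- function(pd, params, grid) {
  p <- as_param_vectors(params)
  g <- as_grid(grid)
  res <- estep_cpp(pd$U, pd$O, pd$f, p$a, p$c, g$nodes, g$weights,
                   scores = TRUE)
  res$scores
}

#' Empirical cross-product (XPD) information matrix
#'
#' Approximates the information matrix by the frequency-weighted sum of
#' outer products of per-pattern marginal score vectors,
#' `I_xpd = sum_r f_r v_r v_r'`.  Information is additive over independent
#' observations, so `xpd_accumulate()` can build the same matrix
#' incrementally over disjoint data subsets — this is how the two-stage
#' algorithm obtains standard errors without an extra full-data pass.
#'
#' @param data Response matrix/data frame or `pattern_data`.
#' @param params Item parameter table at which scores are evaluated.
#' @param grid Quadrature grid.
#' @return Symmetric `2I x 2I` matrix with attributes `kind = "xpd"` and
#'   `n_eff` (number of persons accumulated).
#' @export
xpd_information <- function(data, params, grid = quadrature_grid()) {
  pd <- if (inherits(data, "pattern_data")) data else compress_patterns(data)
  running <- matrix(0, 2 * ncol(pd$U), 2 * ncol(pd$U))
  dimnames(running) <- list(param_labels(ncol(pd$U)), param_labels(ncol(pd$U)))
  running <- structure(running, kind = "xpd", n_eff = 0)
  xpd_accumulate(running, pd, params, grid)
}

#' @rdname xpd_information
#' @param running A `2I x 2I` matrix to add to (e.g. a zero matrix or the
#'   result of a previous accumulation).
#' @export
xpd_accumulate <- function(running, data, params, grid = quadrature_grid()) {
  pd <- if (inherits(data, "pattern_data")) data else compress_patterns(data)
  if (!all(dim(running) == 2 * ncol(pd$U))) {
    abort(sprintf("`running` must be %d x %d.", 2 * ncol(pd$U), 2 * ncol(pd$U)))
  }
  V <- score_matrix(pd, params, grid)
  out <- running + crossprod(V, V * pd$f)
  structure(out, kind = "xpd",
            n_eff = (attr(running, "n_eff") %||% 0) + pd$n_persons,
            dimnames = dimnames(running))
}

#' Fisher expected information by response-pattern enumeration
#'
#' The expected information of a single observation,
#' `F = sum_r pi_r s_r s_r'`, where the sum runs over all `2^I` fully
#' observed response patterns, `pi_r` is the marginal pattern probability
#' under the model and `s_r` the pattern's score vector.  (Equivalently
#' `J' diag(pi)^{-1} J` with `J` the matrix of probability gradients
#' `pi_r s_r`.)  This is the gold standard for standard errors in
#' simulation work: at true parameters and sample size `n`, SEs are the
#' square roots of `diag([n F]^{-1})`.
#'
#' Enumeration cost grows as `2^I`; item counts above `max_items` are
#' refused.  Patterns are processed in blocks so memory stays flat.
#'
#' @param params Item parameter table (columns `a`, `c`).
#' @param grid Quadrature grid.
#' @param max_items Enumeration guard (default 20).
#' @return Symmetric `2I x 2I` matrix with attributes `kind = "fis"` and
#'   `total_prob` (the enumerated probability mass, equal to 1 up to
#'   numerical error).
#' @examples
#' fisher_information(item_params(a = c(1, 1.4), c = c(0, -0.3)))
#' @export
fisher_information <- function(params, grid = quadrature_grid(),
                               max_items = 20) {
  p <- as_param_vectors(params)
  I <- length(p$a)
  if (I > max_items) {
    abort(sprintf(
      "Fisher enumeration over 2^%d patterns refused (max_items = %d); use XPD standard errors instead.",
      I, max_items))
  }
  g <- as_grid(grid)
  Fmat <- matrix(0, 2 * I, 2 * I)
  total <- 0
  block_bits <- min(I, 14L)
  Ublock <- enum_pattern_matrix(block_bits)
  n_blocks <- 2L^(I - block_bits)
  O <- matrix(1, nrow(Ublock), I)
  for (blk in seq_len(n_blocks) - 1L) {
    U <- if (n_blocks == 1L) {
      Ublock
    } else {
      hi <- blk %/% 2L^(0:(I - block_bits - 1L)) %% 2L
      cbind(Ublock, matrix(hi, nrow(Ublock), I - block_bits, byrow = TRUE))
    }
    res <- estep_cpp(U, O, rep(1, nrow(U)), p$a, p$c, g$nodes, g$weights,
                     scores = TRUE)
    pi_r <- as.numeric(exp(res$pattern_loglik))
    Fmat <- Fmat + crossprod(res$scores, res$scores * pi_r)
    total <- total + sum(pi_r)
  }
  dimnames(Fmat) <- list(param_labels(I), param_labels(I))
  structure(Fmat, kind = "fis", total_prob = total, n_patterns = 2^I)
}

#' Standard errors from an information matrix
#'
#' Inverts the (scaled) information matrix and returns the square roots of
#' the diagonal of the resulting covariance matrix, ordered
#' `(a_1, c_1, ..., a_I, c_I)`.  An XPD matrix already carries the sample
#' size through the pattern frequencies, so `n = 1`; a Fisher
#' expected-information matrix is per observation and must be scaled by the
#' sample size.
#'
#' @param info Symmetric information matrix ([xpd_information()] or
#'   [fisher_information()]).
#' @param n Scaling sample size (default 1).
#' @return Named numeric vector of standard errors.
#' @export
se_from_information <- function(info, n = 1) {
  m <- unclass(info) * n
  attributes(m) <- list(dim = dim(info), dimnames = dimnames(info))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || !all(is.finite(ev))) {
    v <- eigen(m, symmetric = TRUE)$vectors[, which.min(ev)]
    culprit <- order(abs(v), decreasing = TRUE)[1:2]
    labs <- dimnames(m)[[1]] %||% as.character(seq_len(nrow(m)))
    abort(sprintf("Information matrix is singular; null space loads on %s.",
                  paste(labs[culprit], collapse = ", ")))
  }
  if (max(ev) / min(ev) > 1e10) {
    warn(sprintf("Information matrix is ill-conditioned (kappa = %.2e).",
                 max(ev) / min(ev)))
  }
  covm <- chol2inv(chol(m))
  setNames(sqrt(diag(covm)),
           dimnames(m)[[1]] %||% param_labels(nrow(m) / 2))
}

#' Standard-error table from true parameters (gold standard)
#'
#' Convenience wrapper: Fisher expected information at the supplied
#' parameters, scaled to sample size `n`, returned per item.
#'
#' @param params Item parameter table.
#' @param n Sample size.
#' @param grid Quadrature grid.
#' @return Tibble with columns `item`, `a`, `se_a`, `c`, `se_c`, `b`.
#' @export
fisher_se_table <- function(params, n, grid = quadrature_grid()) {
  p <- as_param_vectors(params)
  se <- se_from_information(fisher_information(params, grid), n = n)
  tibble::tibble(item = p$item, a = p$a,
                 se_a = unname(se[seq(1, length(se), 2)]),
                 c = p$c, se_c = unname(se[seq(2, length(se), 2)]),
                 b = ifelse(p$a == 0, NA_real_, -p$c / p$a))
}
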