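# Independent brute-force oracles used across the suite.  These deliberately
# loop over patterns and nodes in plain R so they share no code with the
# package's vectorized/compiled implementations.

# marginal log-likelihood by direct summation
brute_loglik <- function(U, f, a, c, nodes, weights) {
  total <- 0
  for (r in seq_len(nrow(U))) {
    lik_k <- numeric(length(nodes))
    for (k in seq_along(nodes)) {
      lik <- 1
      for (i in seq_along(a)) {
        u <- U[r, i]
        if (!is.na(u)) {
          p <- 1 / (1 + exp(-(a[i] * nodes[k] + c[i])))
          lik <- lik * if (u == 1) p else (1 - p)
        }
      }
      lik_k[k] <- weights[k] * lik
    }
    total <- total + f[r] * log(sum(lik_k))
  }
  total
}

# expected counts by direct summation over patterns and nodes
brute_counts <- function(U, f, a, c, nodes, weights) {
  I <- length(a); K <- length(nodes)
  r1 <- matrix(0, I, K); r0 <- matrix(0, I, K)
  for (r in seq_len(nrow(U))) {
    post <- numeric(K)
    for (k in seq_len(K)) {
      lik <- 1
      for (i in seq_len(I)) {
        u <- U[r, i]
        if (!is.na(u)) {
          p <- 1 / (1 + exp(-(a[i] * nodes[k] + c[i])))
          lik <- lik * if (u == 1) p else (1 - p)
        }
      }
      post[k] <- weights[k] * lik
    }
    post <- post / sum(post)
    for (i in seq_len(I)) {
      u <- U[r, i]
      if (!is.na(u)) {
        if (u == 1) r1[i, ] <- r1[i, ] + f[r] * post
        else r0[i, ] <- r0[i, ] + f[r] * post
      }
    }
  }
  list(r1 = r1, r0 = r0, n_tilde = r1 + r0)
}

# central finite differences of a scalar function
num_grad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

small_bank <- function() {
  item_params(a = c(0.9, 1.6, 1.2, 0.7), c = c(0.4, -0.8, 1.1, -0.2))
}

# fast two-stage control for unit tests where convergence depth is not the
# point of the test
quick_ctrl <- function(...) {
  em_control(max_epochs = 12, warmup = 5, window = 4, ...)
}
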