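test_that("E-step counts match closed forms and conserve persons", {
  g <- quadrature_grid(7, 3)
  # one person answering 1 on a flat item: posterior = prior, so r1 = w
  cnt <- e_step(matrix(1), item_params(a = 0, c = 0), g)
  expect_equal(as.numeric(cnt$r1), g$weight)
  expect_equal(as.numeric(cnt$r0), rep(0, 7))
  # count conservation per item, including under missingness
  y <- rbind(c(1, 0, NA), c(0, NA, 1), c(1, 1, 1), c(0, 0, 0))
  params <- item_params(a = c(1, 0.5, 2), c = c(0, 1, -1))
  cnt <- e_step(y, params, g)
  expect_equal(rowSums(cnt$n_tilde), colSums(!is.na(y)))
})

test_that("E-step counts equal brute-force summation over patterns and nodes", {
  g <- quadrature_grid(3, 1)
  params <- item_params(a = c(0.8, 1.5), c = c(-0.2, 0.6))
  y <- rbind(c(1, 0), c(0, 0))
  cnt <- e_step(y, params, g)
  oracle <- brute_counts(y, c(1, 1), params$a, params$c, g$node, g$weight)
  expect_equal(cnt$r1, oracle$r1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cnt$r0, oracle$r0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Q-function gradient and Hessian agree with finite-difference oracles", {
  set.seed(21)
  g <- quadrature_grid(21, 4)
  bank <- small_bank()
  y <- simulate_2pl(bank, 500, seed = 6)
  counts <- e_step(y, bank, g)
  for (i in c(1, 3)) {
    phi0 <- c(bank$a[i] + 0.1, bank$c[i] - 0.2)
    qfun <- function(phi) {
      pars <- bank
      pars$a[i] <- phi[1]; pars$c[i] <- phi[2]
      q_value(counts, pars, g, item = i)
    }
    pars0 <- bank; pars0$a[i] <- phi0[1]; pars0$c[i] <- phi0[2]
    gr <- q_gradient(counts, pars0, g, item = i)
    expect_equal(unname(gr), num_grad(qfun, phi0), tolerance = 1e-6)
    h <- q_hessian(counts, pars0, g, item = i)
    gfun_a <- function(phi) {
      pars <- bank; pars$a[i] <- phi[1]; pars$c[i] <- phi[2]
      q_gradient(counts, pars, g, item = i)[["a"]]
    }
    gfun_c <- function(phi) {
      pars <- bank; pars$a[i] <- phi[1]; pars$c[i] <- phi[2]
      q_gradient(counts, pars, g, item = i)[["c"]]
    }
    H_num <- rbind(num_grad(gfun_a, phi0), num_grad(gfun_c, phi0))
    expect_equal(unname(unclass(h)), unname(H_num), tolerance = 1e-5)
    expect_identical(h[1, 2], h[2, 1])   # exact symmetry
  }
})

test_that("degenerate counts give exactly zero gradient and Hessian", {
  g <- quadrature_grid(5, 2)
  I <- 2; K <- 5
  # r1 = n * P pointwise: stationary point of Q
  params <- item_params(a = c(1, 2), c = c(0, -1))
  P <- t(plogis(outer(g$node, params$a) + rep(params$c, each = K)))
  n <- matrix(10, I, K)
  counts <- list(r1 = n * P, r0 = n * (1 - P), n_tilde = n)
  expect_equal(unname(q_gradient(counts, params, g, 1)), c(0, 0))
  zero <- list(r1 = matrix(0, I, K), r0 = matrix(0, I, K),
               n_tilde = matrix(0, I, K))
  expect_equal(unclass(q_hessian(zero, params, g, 2)),
               matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("the exact M-step maximizes Q: ascent property and grid-search oracle", {
  set.seed(31)
  g <- quadrature_grid(21, 4)
  bank <- small_bank()
  y <- simulate_2pl(bank, 800, seed = 13)
  counts <- e_step(y, bank, g)
  start <- item_params(a = rep(1, 4), c = rep(0, 4))
  opt <- m_step_full(counts, start, g)
  for (i in 1:4) {
    expect_gte(q_value(counts, opt, g, i), q_value(counts, start, g, i))
  }
  # grid search refined around the Newton solution for one item
  i <- 2
  qfun <- function(a, c) {
    pars <- bank; pars$a[i] <- a; pars$c[i] <- c
    q_value(counts, pars, g, item = i)
  }
  coarse <- expand.grid(a = seq(0.2, 3, by = 0.05),
                        c = seq(-3, 3, by = 0.05))
  best <- coarse[which.max(mapply(qfun, coarse$a, coarse$c)), ]
  fine <- expand.grid(a = seq(best$a - 0.06, best$a + 0.06, by = 0.001),
                      c = seq(best$c - 0.06, best$c + 0.06, by = 0.001))
  best2 <- fine[which.max(mapply(qfun, fine$a, fine$c)), ]
  expect_lt(abs(opt$a[i] - best2$a), 1.5e-3)
  expect_lt(abs(opt$c[i] - best2$c), 1.5e-3)
})

test_that("the M-step recovers the generating values from model-consistent counts", {
  g <- quadrature_grid(49, 6)
  K <- 49
  P <- t(plogis(outer(g$node, c(1)) + 0))       # item (a, c) = (1, 0)
  n <- matrix(1e5 * g$weight, 1, K, byrow = TRUE)
  counts <- list(r1 = n * P, r0 = n * (1 - P), n_tilde = n)
  opt <- m_step_full(counts, item_params(a = 1.8, c = 0.9), g)
  expect_equal(opt$a, 1, tolerance = 1e-8)
  expect_equal(opt$c, 0, tolerance = 1e-8)
})

test_that("standard EM is monotone in marginal log-likelihood and order-invariant", {
  y <- simulate_2pl(small_bank(), 600, seed = 17)
  fit <- fit_2pl(y, method = "standard")
  ll <- fit$trajectory$loglik
  expect_true(all(diff(ll) >= -1e-8))
  expect_true(fit$converged)
  # compressed and raw data give identical estimates
  fit_pd <- fit_2pl(compress_patterns(y), method = "standard")
  expect_equal(fit$estimates$a, fit_pd$estimates$a, tolerance = 1e-12)
  # at convergence the per-item Q-gradients and the total score vanish
  g <- quadrature_grid()
  counts <- e_step(y, fit$estimates, g)
  for (i in 1:4) {
    expect_lt(max(abs(q_gradient(counts, fit$estimates, g, i))), 1e-4)
  }
  pd <- compress_patterns(y)
  V <- emirt:::score_matrix(pd, fit$estimates, g)
  expect_lt(max(abs(colSums(V * pd$f))), 1e-4)
})

test_that("zero-variance items are rejected before estimation", {
  y <- cbind(a = rep(1, 50), b = sample(0:1, 50, replace = TRUE))
  expect_error(fit_2pl(y, method = "standard"), "zero observed variance")
})

test_that("standard EM recovers a known slope within three gold standard errors", {
  bank <- item_bank("se12")
  y <- simulate_2pl(bank, 60000, seed = 20)
  fit <- fit_2pl(compress_patterns(y), method = "standard")
  expect_lt(abs(fit$estimates$a[1] - 0.68), 3 * 0.015)
})
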