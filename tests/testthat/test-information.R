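test_that("marginal scores have closed-form and finite-difference values", {
  g <- quadrature_grid(15, 4)
  # flat single item answered 1: dl/dc = sum_k g_k (1 - 0.5) = 0.5
  s <- marginal_score(1, item_params(a = 0, c = 0), g)
  expect_equal(unname(s), c(0, 0.5))
  # finite differences of the per-pattern log marginal likelihood
  bank <- small_bank()
  pattern <- c(1, 0, NA, 1)
  llfun <- function(phi) {
    pars <- item_params(a = phi[seq(1, 8, 2)], c = phi[seq(2, 8, 2)])
    marginal_loglik(matrix(pattern, nrow = 1), pars, g)
  }
  phi0 <- as.vector(rbind(bank$a, bank$c))
  s <- marginal_score(pattern, bank, g)
  expect_equal(unname(s), num_grad(llfun, phi0), tolerance = 1e-6)
  # unobserved items contribute exactly zero
  expect_identical(unname(s[c("a_3", "c_3")]), c(0, 0))
})

test_that("the total score vanishes at the standard-EM solution", {
  y <- simulate_2pl(small_bank(), 700, seed = 73)
  fit <- fit_2pl(y, method = "standard")
  pd <- compress_patterns(y)
  V <- emirt:::score_matrix(pd, fit$estimates, quadrature_grid())
  expect_lt(max(abs(colSums(V * pd$f))), 1e-4)
})

test_that("XPD is a frequency-weighted sum of score outer products", {
  g <- quadrature_grid(21, 4)
  bank <- small_bank()
  # single pattern with f = 1: rank-one matrix v v'
  one <- matrix(c(1, 0, 1, 1), nrow = 1)
  info <- xpd_information(one, bank, g)
  v <- marginal_score(c(1, 0, 1, 1), bank, g)
  expect_equal(unclass(info), outer(v, v), ignore_attr = TRUE)
  # additivity over a partition, and symmetry / PSD
  y <- as_response_matrix(simulate_2pl(bank, 200, seed = 79))
  full <- xpd_information(y, bank, g)
  pd <- compress_patterns(y)
  plan <- make_subsets(200, 0.4, seed = 6)
  acc <- matrix(0, 8, 8)
  for (s in seq_along(plan)) {
    acc <- xpd_accumulate(acc, subset_patterns(pd, plan, s), bank, g)
  }
  expect_equal(unclass(acc), unclass(full), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(full), t(unclass(full)))
  expect_true(min(eigen(full, symmetric = TRUE)$values) > -1e-8)
  expect_equal(attr(acc, "n_eff"), 200)
})

test_that("Fisher enumeration is exhaustive and matches a brute-force oracle", {
  params <- item_params(a = c(1.3, 0.7), c = c(0.4, -1.1))
  Fm <- fisher_information(params)
  expect_equal(attr(Fm, "total_prob"), 1, tolerance = 1e-10)
  expect_equal(attr(Fm, "n_patterns"), 4)
  # dense-grid double loop over the four patterns (independent of the
  # package quadrature: 20001-point trapezoid on [-8, 8])
  eta <- seq(-8, 8, length.out = 20001)
  w <- dnorm(eta); w <- w / sum(w)
  P <- plogis(outer(eta, params$a) + rep(params$c, each = length(eta)))
  oracle <- matrix(0, 4, 4)
  for (u1 in 0:1) for (u2 in 0:1) {
    lik <- (u1 * P[, 1] + (1 - u1) * (1 - P[, 1])) *
      (u2 * P[, 2] + (1 - u2) * (1 - P[, 2]))
    pi_r <- sum(w * lik)
    post <- w * lik / pi_r
    s <- c(sum(post * (u1 - P[, 1]) * eta), sum(post * (u1 - P[, 1])),
           sum(post * (u2 - P[, 2]) * eta), sum(post * (u2 - P[, 2])))
    oracle <- oracle + pi_r * outer(s, s)
  }
  expect_equal(unclass(Fm), oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("one-item Fisher information equals the marginal Bernoulli closed form", {
  # with a single item the marginal model is Bernoulli(pi) with
  # pi = int P dPhi, so the expected information about (a, c) is the
  # rank-one matrix (grad pi)(grad pi)' / (pi (1 - pi)), with
  # grad pi = (int P Q eta dPhi, int P Q dPhi); dense-grid oracle
  a <- 1.4; c <- -0.6
  Fm <- fisher_information(item_params(a = a, c = c))
  eta <- seq(-8, 8, length.out = 40001)
  w <- dnorm(eta); w <- w / sum(w)
  P <- plogis(a * eta + c)
  pi1 <- sum(w * P)
  dpi <- c(sum(w * P * (1 - P) * eta), sum(w * P * (1 - P)))
  oracle <- outer(dpi, dpi) / (pi1 * (1 - pi1))
  expect_equal(unclass(Fm), oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # and it is singular: one Bernoulli cannot identify two parameters
  expect_lt(det(unclass(Fm)) / max(abs(Fm))^2, 1e-10)
})

test_that("Fisher enumeration is refused beyond the guard", {
  big <- item_params(a = rep(1, 25), c = rep(0, 25))
  expect_error(fisher_information(big), "refused")
})

test_that("full-data XPD at true parameters approaches N times the Fisher information", {
  bank <- small_bank()
  n <- 40000
  y <- simulate_2pl(bank, n, seed = 83)
  se_xpd <- se_from_information(xpd_information(y, bank))
  se_fis <- se_from_information(fisher_information(bank), n = n)
  expect_lt(max(abs(se_xpd / se_fis - 1)), 0.05)
})

test_that("standard errors invert the scaled information", {
  d <- c(4, 25, 100)
  info <- diag(d)
  expect_equal(unname(se_from_information(info)), 1 / sqrt(d))
  expect_equal(unname(se_from_information(info, n = 4)), 0.5 / sqrt(d))
  sing <- matrix(c(1, 1, 1, 1), 2,
                 dimnames = list(c("a_1", "c_1"), c("a_1", "c_1")))
  expect_error(se_from_information(sing), "singular")
})

test_that("the enumeration kernel agrees with the generic pattern kernel", {
  set.seed(89)
  g <- emirt:::as_grid(quadrature_grid())
  for (rep in 1:5) {
    I <- sample(3:8, 1)
    a <- runif(I, 0.4, 3); cc <- runif(I, -3, 3)
    f <- as.numeric(rmultinom(1, 500, runif(2^I)))
    U <- emirt:::enum_pattern_matrix(I)
    e1 <- emirt:::estep_cpp(U, matrix(1, 2^I, I), f, a, cc, g$nodes,
                            g$weights)
    e2 <- emirt:::estep_enum_cpp(f, a, cc, g$nodes, g$weights)
    expect_equal(e1$r1, e2$r1, tolerance = 1e-12)
    expect_equal(e1$loglik, e2$loglik, tolerance = 1e-12)
    n1 <- e1$r1 + e1$r0
    expect_equal(n1[1, ], as.numeric(e2$nk), tolerance = 1e-12)
  }
})
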