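test_that("the switching rule exponentiates the negative log-likelihood change", {
  expect_equal(switching_delta(-500, -500), 1)
  expect_equal(switching_delta(-500, NULL), 0)
  expect_equal(switching_delta(-500, NA), 0)
  expect_equal(switching_delta(-500, -500 - log(2)), 0.5)
})

test_that("partial E-step counts are additive over any partition of the data", {
  y <- as_response_matrix(simulate_2pl(small_bank(), 150, seed = 23))
  g <- quadrature_grid(15, 4)
  params <- item_params(a = c(1.1, 0.9, 1.4, 0.6), c = c(0, 0.5, -0.7, 0.2))
  full <- e_step(y, params, g)
  plan <- make_subsets(150, 0.35, seed = 5)
  pd <- compress_patterns(y)
  acc1 <- 0; acc0 <- 0
  for (s in seq_along(plan)) {
    sub <- e_step(subset_patterns(pd, plan, s), params, g)
    acc1 <- acc1 + sub$r1; acc0 <- acc0 + sub$r0
  }
  expect_equal(acc1, full$r1, tolerance = 1e-10)
  expect_equal(acc0, full$r0, tolerance = 1e-10)
})

test_that("a fraction-one subset reproduces the full E-step bit for bit", {
  y <- as_response_matrix(simulate_2pl(small_bank(), 80, seed = 29))
  pd <- compress_patterns(y)
  params <- small_bank()
  sub <- subset_patterns(pd, make_subsets(80, 1, seed = 1), 1)
  expect_identical(e_step(sub, params)$r1, e_step(pd, params)$r1)
})

test_that("the damped M-update is a Newton ascent step of the requested length", {
  set.seed(37)
  g <- quadrature_grid(21, 4)
  bank <- small_bank()
  counts <- e_step(simulate_2pl(bank, 400, seed = 41), bank, g)
  start <- item_params(a = rep(1, 4), c = rep(0, 4))
  # gamma = 1 lands exactly at phi - H^{-1} grad, assembled independently
  one <- modified_m_step(start, counts, g, gamma = 1)
  for (i in 1:4) {
    gr <- q_gradient(counts, start, g, i)
    h <- q_hessian(counts, start, g, i)
    step <- solve(h, gr)
    expect_equal(c(one$a[i], one$c[i]),
                 c(start$a[i] - step[1], start$c[i] - step[2]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # gamma = 0.5 moves half as far, against a finite-difference oracle
  half <- modified_m_step(start, counts, g, gamma = 0.5)
  i <- 2
  qfun <- function(phi) {
    pars <- start; pars$a[i] <- phi[1]; pars$c[i] <- phi[2]
    q_value(counts, pars, g, item = i)
  }
  phi0 <- c(1, 0)
  g_num <- num_grad(qfun, phi0)
  H_num <- rbind(num_grad(function(p) num_grad(qfun, p)[1], phi0, h = 1e-4),
                 num_grad(function(p) num_grad(qfun, p)[2], phi0, h = 1e-4))
  step <- solve(H_num, g_num)
  expect_equal(c(half$a[i], half$c[i]), phi0 - 0.5 * step, tolerance = 1e-4)
  # zero gradient: parameters unchanged for any gamma
  K <- 21
  P <- t(plogis(outer(g$node, start$a) + rep(start$c, each = K)))
  n <- matrix(5, 4, K)
  fixed <- list(r1 = n * P, r0 = n * (1 - P), n_tilde = n)
  same <- modified_m_step(start, fixed, g, gamma = 0.7)
  expect_equal(same$a, start$a)
  expect_equal(same$c, start$c)
})

test_that("iterate averaging starts after warm-up and tracks the running mean", {
  st <- new_average_state(2, warmup = 3, window = 5)
  for (x in list(c(10, 10), c(20, 20), c(30, 30))) {
    st <- update_average(st, x)
    expect_null(st$mean)            # warm-up: mean undefined
    expect_equal(st$working, x)     # raw iterate propagated
  }
  for (v in 1:5) st <- update_average(st, c(v, 2 * v))
  expect_equal(st$mean, c(3, 6))    # mean of 1..5 and 2,4,...,10
  expect_equal(st$working, st$mean)
  # symmetric oscillation averages to its center
  st2 <- new_average_state(1, warmup = 0, window = 3)
  for (k in 1:400) st2 <- update_average(st2, 5 + c(-1, 1)[k %% 2 + 1] * 0.3)
  expect_equal(st2$mean, 5, tolerance = 1e-9)
})

test_that("stability checking thresholds the variance of recent averaged values", {
  base <- new_average_state(1, warmup = 0, window = 10)
  base$window_size <- 10
  set.seed(3)
  v <- rnorm(10)
  scale_to <- function(target_var) {
    x <- v - mean(v)
    matrix(x / sd(x) * sqrt(target_var), ncol = 1)
  }
  base$window <- scale_to(9e-7)
  expect_true(check_stability(base))
  base$window <- scale_to(2e-6)
  expect_false(check_stability(base))
  base$window <- matrix(rep(1.23, 10), ncol = 1)   # identical entries
  expect_true(check_stability(base))
  base$window <- matrix(rep(c(0, 1), 5), ncol = 1)  # variance 0.25 (approx)
  expect_false(check_stability(base))
  base$window <- matrix(rnorm(5), ncol = 1)         # window not yet full
  expect_false(check_stability(base))
})

test_that("a tiny threshold fires the transition at the second stage-1 iteration", {
  y <- simulate_2pl(small_bank(), 400, seed = 47)
  fit <- fit_2pl(y, method = "two_stage", seed = 1,
                 control = quick_ctrl(threshold = 1e-300))
  expect_equal(glance(fit)$transition_iteration, 2L)
  expect_gt(glance(fit)$delta_at_transition, 0)
})

test_that("delta stays in (0, 1] along a monotone stage-1 trajectory", {
  y <- simulate_2pl(small_bank(), 1000, seed = 53)
  fit <- fit_2pl(y, method = "standard")
  d <- fit$trajectory$delta[-1]
  expect_true(all(d > 0 & d <= 1 + 1e-12))
})

test_that("two-stage with full-sample subsets tracks standard EM", {
  # with fraction 1 and gamma 1 every update is a full-data Newton GEM
  # step, so the only difference from standard EM is the averaging of the
  # post-transition transient; the run is deterministic given the data
  y <- simulate_2pl(small_bank(), 20000, seed = 59)
  pd <- compress_patterns(y)
  std <- fit_2pl(pd, method = "standard")
  ts <- fit_2pl(pd, method = "two_stage", seed = 2,
                control = em_control(fraction = 1, gamma = 1, warmup = 0,
                                     max_epochs = 400))
  ts2 <- fit_2pl(pd, method = "two_stage", seed = 9,
                 control = em_control(fraction = 1, gamma = 1, warmup = 0,
                                      max_epochs = 400))
  expect_identical(ts$estimates$a, ts2$estimates$a)
  expect_lt(max(abs(ts$estimates$a - std$estimates$a),
                abs(ts$estimates$c - std$estimates$c)), 0.05)
})

test_that("averaging suppresses subset-shuffle noise at the study scale", {
  y <- simulate_2pl(item_bank("se12"), 60000, seed = 61)
  pd <- compress_patterns(y)
  f1 <- fit_2pl(pd, method = "two_stage", seed = 101)
  f2 <- fit_2pl(pd, method = "two_stage", seed = 202)
  expect_lt(max(abs(f1$estimates$a - f2$estimates$a),
                abs(f1$estimates$c - f2$estimates$c)), 0.02)
})

test_that("an exhausted epoch cap is flagged as non-converged but still estimates", {
  y <- simulate_2pl(small_bank(), 1500, seed = 67)
  fit <- fit_2pl(y, method = "two_stage", seed = 3,
                 control = em_control(max_epochs = 4, warmup = 2, window = 3))
  expect_false(fit$converged)
  expect_equal(glance(fit)$n_stage2_epochs, 4L)
  expect_true(all(is.finite(fit$estimates$a)))
})

test_that("stage-1 early stopping skips stage 2 entirely", {
  y <- simulate_2pl(small_bank(), 800, seed = 71)
  # threshold 1 can never be exceeded (delta <= 1), so stage 1 runs to
  # convergence and returns directly
  fit <- fit_2pl(y, method = "two_stage", seed = 4,
                 control = em_control(threshold = 1))
  expect_true(fit$converged)
  expect_equal(glance(fit)$n_stage2_updates, 0L)
  expect_true(all(fit$trajectory$stage == "stage1"))
})
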