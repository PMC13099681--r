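#' Control parameters for 2PL EM estimation
#'
#' Collects every tunable of the estimation engines in one place.  The
#' defaults are the package's study conditions: 49 equally spaced
#' quadrature nodes on `[-6, 6]`, a 0.90 switching threshold, 20% subsets,
#' damped-Newton step size 0.5, a 30-update averaging warm-up, a stability
#' window of 10 averaged iterates with variance tolerance 1e-6, and a
#' parameter-change convergence tolerance of 1e-6.
#'
#' @param k,bound Quadrature node count and half-range ([quadrature_grid()]).
#' @param tol Convergence tolerance on the largest absolute parameter
#'   change (Stage 1 / standard EM: raw iterates; Stage 2: averaged
#'   iterates).
#' @param max_iter Cap on standard-EM / Stage-1 iterations.
#' @param threshold Stage-1 to Stage-2 switching threshold on the
#'   exponentiated log-likelihood change `delta`, in (0, 1].
#' @param fraction Stage-2 subset size as a fraction of the sample, (0, 1].
#' @param gamma Fixed damped-Newton step size in (0, 1].
#' @param warmup Number of Stage-2 updates before iterate averaging starts.
#' @param window Number of recent averaged iterates kept for the stability
#'   check.
#' @param stability_tol Variance threshold for the stability window.
#' @param max_epochs Cap on Stage-2 epochs (full passes over the subsets).
#' @param reshuffle Re-shuffle and re-partition persons at the start of
#'   every Stage-2 epoch (default `TRUE`); `FALSE` keeps a single fixed
#'   partition.
#' @param enum_limit Fully observed data with at most this many items use a
#'   complete-enumeration E-step kernel (cost `O(2^I K)`); larger or
#'   incomplete data use the generic pattern kernel.
#' @param compute_se Compute XPD standard errors as part of the fit.
#' @param inner_tol,inner_max Newton tolerance and iteration cap inside the
#'   exact M-step.
#' @return A named list of class `em_control`.
#' @export
em_control <- function(k = 49, bound = 6, tol = 1e-6, max_iter = 2000,
                       threshold = 0.9, fraction = 0.2, gamma = 0.5,
                       warmup = 30, window = 10, stability_tol = 1e-6,
                       max_epochs = 200, reshuffle = TRUE, enum_limit = 13,
                       compute_se = TRUE, inner_tol = 1e-10, inner_max = 50) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  structure(list(k = k, bound = bound, tol = tol, max_iter = max_iter,
                 threshold = threshold, fraction = fraction, gamma = gamma,
                 warmup = warmup, window = window,
                 stability_tol = stability_tol, max_epochs = max_epochs,
                 reshuffle = reshuffle, enum_limit = enum_limit,
                 compute_se = compute_se, inner_tol = inner_tol,
                 inner_max = inner_max),
            class = "em_control")
}

#' Switching rule between Stage 1 and Stage 2
#'
#' The exponentiated negative log-likelihood improvement,
#' `delta = exp(-(ll_now - ll_prev))`.  On a monotone EM trajectory delta
#' lies in (0, 1] and approaches 1 as improvements vanish; the two-stage
#' algorithm leaves full-data EM once delta exceeds its threshold.  At the
#' first iteration, where no previous log-likelihood exists, delta is 0.
#'
#' @param ll_now Current marginal log-likelihood.
#' @param ll_prev Previous value, or `NULL`/`NA` at the first iteration.
#' @return A single non-negative number.
#' @examples
#' switching_delta(-100, -100 - log(2))  # 0.5
#' @export
switching_delta <- function(ll_now, ll_prev = NULL) {
  if (is.null(ll_prev) || is.na(ll_prev)) return(0)
  exp(-(ll_now - ll_prev))
}

#' Running-average state for Stage-2 iterate averaging
#'
#' Stage 2's fixed-step Newton updates oscillate in a noise ball around the
#' MLE; the running mean of post-warm-up iterates tracks the center of that
#' oscillation.  `new_average_state()` initializes the bookkeeping,
#' `update_average()` folds in one iterate, and `check_stability()` tests
#' whether the per-parameter variance of the last `window` averaged values
#' has fallen below the stability tolerance.
#'
#' During the warm-up the running mean is undefined and `$working` carries
#' the raw iterate; afterwards it carries the running mean (which is what
#' gets fed back into the next partial E-step).
#'
#' @param n_params Length of the parameter vector.
#' @param warmup Updates to skip before averaging starts.
#' @param window Number of recent averaged iterates retained.
#' @param stability_tol Variance threshold for stability.
#' @return `new_average_state()`/`update_average()`: the state list
#'   (`count`, `n_post`, `mean`, `window`, `working`);
#'   `check_stability()`: `TRUE`/`FALSE` (`FALSE` while the window is not
#'   yet full).
#' @export
new_average_state <- function(n_params, warmup = 30, window = 10,
                              stability_tol = 1e-6) {
  list(count = 0L, warmup = as.integer(warmup), n_post = 0L,
       mean = NULL, window = matrix(numeric(0), 0, n_params),
       window_size = as.integer(window), stability_tol = stability_tol,
       working = NULL)
}

#' @rdname new_average_state
#' @param state An averaging state.
#' @param iterate Numeric parameter vector for the newest update.
#' @export
update_average <- function(state, iterate) {
  state$count <- state$count + 1L
  if (state$count <= state$warmup) {
    state$working <- iterate
    return(state)
  }
  state$n_post <- state$n_post + 1L
  state$mean <- if (state$n_post == 1L) {
    iterate
  } else {
    state$mean + (iterate - state$mean) / state$n_post
  }
  state$window <- rbind(state$window, state$mean)
  if (nrow(state$window) > state$window_size) {
    state$window <- state$window[-1, , drop = FALSE]
  }
  state$working <- state$mean
  state
}

#' @rdname new_average_state
#' @export
check_stability <- function(state) {
  if (nrow(state$window) < state$window_size) return(FALSE)
  all(apply(state$window, 2, var) < state$stability_tol)
}

# ---------------------------------------------------------------------------
# data preparation shared by the engines

prep_fit_data <- function(data, control) {
  if (inherits(data, "pattern_data")) {
    pd <- data
    m <- NULL
  } else {
    m <- as_response_matrix(data, check_variance = TRUE)
    pd <- compress_patterns(m)
  }
  enum <- NULL
  if (ncol(pd$U) <= control$enum_limit && all(pd$O == 1) &&
      !is.null(pd$row_index)) {
    # map each person to a cell of the full 2^I enumeration
    id_pat <- as.integer(pd$U %*% 2^(seq_len(ncol(pd$U)) - 1)) + 1L
    enum <- list(id = id_pat[pd$row_index], n_patterns = 2L^ncol(pd$U))
    enum$f_full <- tabulate(enum$id, nbins = enum$n_patterns)
  }
  list(pd = pd, enum = enum, n_persons = pd$n_persons,
       n_items = ncol(pd$U), items = pd$items)
}

# full-data E-step through the fastest available kernel
full_e_step <- function(prep, a, c, g) {
  if (!is.null(prep$enum)) {
    e_step_enum(prep$enum$f_full, a, c, g)
  } else {
    pd <- prep$pd
    res <- estep_cpp(pd$U, pd$O, pd$f, a, c, g$nodes, g$weights)
    list(r1 = res$r1, r0 = res$r0, n_tilde = res$r1 + res$r0,
         loglik = res$loglik)
  }
}

subset_e_step <- function(prep, idx, a, c, g) {
  if (!is.null(prep$enum)) {
    f_s <- tabulate(prep$enum$id[idx], nbins = prep$enum$n_patterns)
    e_step_enum(f_s, a, c, g)
  } else {
    pd <- prep$pd
    f_s <- tabulate(pd$row_index[idx], nbins = length(pd$f))
    keep <- f_s > 0
    res <- estep_cpp(pd$U[keep, , drop = FALSE], pd$O[keep, , drop = FALSE],
                     f_s[keep], a, c, g$nodes, g$weights)
    list(r1 = res$r1, r0 = res$r0, n_tilde = res$r1 + res$r0,
         loglik = res$loglik)
  }
}

# score pass for a subset at given parameters -> XPD contribution
subset_xpd <- function(prep, idx, a, c, g) {
  pd <- prep$pd
  f_s <- tabulate(pd$row_index[idx], nbins = length(pd$f))
  keep <- f_s > 0
  res <- estep_cpp(pd$U[keep, , drop = FALSE], pd$O[keep, , drop = FALSE],
                   f_s[keep], a, c, g$nodes, g$weights, scores = TRUE)
  crossprod(res$scores, res$scores * f_s[keep])
}

# ---------------------------------------------------------------------------

#' Fit a unidimensional 2PL model by marginal maximum likelihood
#'
#' @description
#' `fit_2pl()` estimates item slopes and intercepts from a person-by-item
#' 0/1 response table (with `NA` for planned missingness), integrating the
#' standard-normal latent trait out by fixed quadrature.
#'
#' * `method = "standard"`: classical Bock-Aitkin EM — full-data E-step and
#'   exact per-item Newton M-step, iterated until the largest absolute
#'   parameter change drops below `control$tol`.
#' * `method = "two_stage"`: the accelerated algorithm.  Stage 1 runs
#'   standard EM until the switching rule [switching_delta()] exceeds
#'   `control$threshold` (signalling the neighbourhood of the MLE), then
#'   Stage 2 cycles over shuffled disjoint person subsets, each visited by
#'   a partial E-step and a single damped Newton M-update, with post
#'   warm-up iterate averaging.  Stage 2 stops when the averaged iterates
#'   change by less than `control$tol` and their recent variance passes the
#'   stability check; it never evaluates the full-data log-likelihood.
#'
#' Standard errors come from the empirical cross-product (XPD) information
#' matrix: accumulated over the final epoch's subsets for the two-stage
#' method, or from one full-data score pass for standard EM.
#'
#' @param data Response matrix or data frame (persons x items, cells
#'   0/1/`NA`), or a `pattern_data` object.
#' @param method `"standard"` or `"two_stage"`.
#' @param control An [em_control()] list.
#' @param start Optional starting item parameters (default: all slopes 1,
#'   all intercepts 0).
#' @param seed Optional integer seed covering all internal randomness (the
#'   Stage-2 subset shuffles); the caller's RNG state is preserved.
#' @return An object of class `em2pl`; see [tidy.em2pl()], [glance.em2pl()]
#'   and [autoplot.em2pl()] for tidy access, and `$trajectory` for the
#'   per-iteration log.
#' @examples
#' bank <- item_params(a = c(1, 1.5, 0.8), c = c(0, -0.5, 0.5))
#' y <- simulate_2pl(bank, n = 400, seed = 1)
#' fit <- fit_2pl(y, method = "standard", control = em_control(tol = 1e-4))
#' tidy(fit)
#' @export
fit_2pl <- function(data, method = c("standard", "two_stage"),
                    control = em_control(), start = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(control, "em_control"))
  run <- function() {
    prep <- prep_fit_data(data, control)
    grid <- quadrature_grid(control$k, control$bound)
    g <- as_grid(grid)
    start_p <- if (is.null(start)) {
      list(a = rep(1, prep$n_items), c = rep(0, prep$n_items))
    } else {
      as_param_vectors(start)
    }
    t0 <- proc.time()[["elapsed"]]
    if (method == "two_stage" && is.null(prep$enum) &&
        is.null(prep$pd$row_index)) {
      abort(paste("Two-stage estimation needs the person-to-pattern map;",
                  "pass the raw responses or compress_patterns() output."))
    }
    res <- if (method == "standard") {
      engine_standard(prep, g, start_p, control, stage_two = FALSE)
    } else {
      engine_two_stage(prep, g, start_p, control)
    }
    finalize_fit(res, prep, g, grid, control, method,
                 elapsed = proc.time()[["elapsed"]] - t0)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Stage 1 / standard EM.  When stage_two = TRUE the loop additionally
# monitors the switching rule and hands over once delta > threshold.
engine_standard <- function(prep, g, start_p, control, stage_two = FALSE) {
  a <- start_p$a; c <- start_p$c
  ll_prev <- NA_real_
  n <- control$max_iter
  tr_ll <- tr_delta <- tr_change <- rep(NA_real_, n)
  converged <- FALSE
  transitioned <- FALSE
  iter <- 0L
  while (iter < n) {
    iter <- iter + 1L
    counts <- full_e_step(prep, a, c, g)
    ll <- counts$loglik
    delta <- switching_delta(ll, ll_prev)
    upd <- m_step_newton(counts, a, c, g,
                         tol = control$inner_tol, max_iter = control$inner_max)
    change <- max(abs(upd$a - a), abs(upd$c - c))
    tr_ll[iter] <- ll; tr_delta[iter] <- delta; tr_change[iter] <- change
    a <- upd$a; c <- upd$c
    ll_prev <- ll
    if (change < control$tol) {
      converged <- TRUE
      break
    }
    if (stage_two && iter >= 2L && delta > control$threshold) {
      transitioned <- TRUE
      break
    }
  }
  keep <- seq_len(iter)
  list(a = a, c = c, converged = converged, transitioned = transitioned,
       n_iter = iter,
       delta_at_transition = if (transitioned) tr_delta[iter] else NA_real_,
       trajectory = tibble::tibble(
         iteration = keep, stage = "stage1", loglik = tr_ll[keep],
         delta = tr_delta[keep], max_change = tr_change[keep],
         epoch = NA_integer_, subset = NA_integer_))
}

# subset sizes of one epoch: blocks of floor(fraction * P) plus remainder
subset_sizes <- function(P, fraction) {
  size <- max(1L, as.integer(floor(fraction * P)))
  n_full <- P %/% size
  sizes <- rep(size, n_full)
  if (P - n_full * size > 0) sizes <- c(sizes, P - n_full * size)
  as.integer(sizes)
}

# one epoch's partition as a list of subset "handles" consumable by
# stage2_counts()/stage2_xpd(): enum data carries frequency vectors, generic
# data carries person index vectors
epoch_partition <- function(prep, sizes) {
  if (length(sizes) == 1L) {
    return(list(if (!is.null(prep$enum)) list(f = prep$enum$f_full,
                                              n = prep$n_persons)
                else list(idx = seq_len(prep$n_persons),
                          n = prep$n_persons)))
  }
  if (!is.null(prep$enum)) {
    Fs <- shuffle_tabulate_cpp(prep$enum$id, prep$enum$n_patterns, sizes)
    lapply(seq_along(sizes),
           function(s) list(f = Fs[, s], n = sizes[s]))
  } else {
    perm <- sample.int(prep$n_persons)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(sizes),
           function(s) list(idx = perm[starts[s]:ends[s]], n = sizes[s]))
  }
}

stage2_counts <- function(prep, handle, a, c, g) {
  if (!is.null(handle$f)) {
    e_step_enum(handle$f, a, c, g)
  } else {
    subset_e_step(prep, handle$idx, a, c, g)
  }
}

stage2_xpd <- function(prep, handle, a, c, g) {
  if (!is.null(handle$f)) {
    keep <- handle$f > 0
    U <- enum_pattern_matrix(prep$n_items)[keep, , drop = FALSE]
    res <- estep_cpp(U, matrix(1, nrow(U), ncol(U)), handle$f[keep],
                     a, c, g$nodes, g$weights, scores = TRUE)
    crossprod(res$scores, res$scores * handle$f[keep])
  } else {
    subset_xpd(prep, handle$idx, a, c, g)
  }
}

engine_two_stage <- function(prep, g, start_p, control) {
  s1 <- engine_standard(prep, g, start_p, control, stage_two = TRUE)
  if (!s1$transitioned) {
    # Stage-1 early stop (or iteration cap): Stage 2 is skipped entirely
    s1$stage2 <- NULL
    return(s1)
  }
  P <- prep$n_persons
  n_par <- 2L * prep$n_items
  state <- new_average_state(n_par, warmup = control$warmup,
                             window = control$window,
                             stability_tol = control$stability_tol)
  working_a <- s1$a; working_c <- s1$c
  sizes <- subset_sizes(P, control$fraction)
  plan <- epoch_partition(prep, sizes)
  M <- length(plan)
  epoch <- 0L
  update <- 0L
  converged <- FALSE
  stop_subset <- NA_integer_
  # trajectory accumulators and the per-subset working parameters of the
  # current epoch (needed for the deferred XPD accumulation)
  tr_change <- tr_epoch <- tr_subset <- list()
  epoch_params <- vector("list", M)
  while (!converged && epoch < control$max_epochs) {
    epoch <- epoch + 1L
    if (control$reshuffle && epoch > 1L && M > 1L) {
      plan <- epoch_partition(prep, sizes)
    }
    for (s in seq_len(M)) {
      epoch_params[[s]] <- list(a = working_a, c = working_c,
                                handle = plan[[s]])
      counts <- stage2_counts(prep, plan[[s]], working_a, working_c, g)
      Pk <- prob_mat(working_a, working_c, g$nodes)
      gr <- q_gradient_all(counts, working_a, working_c, g$nodes, P = Pk)
      h <- q_hessian_all(counts, working_a, working_c, g$nodes, P = Pk)
      dir <- newton_direction(gr, h)
      bad <- !is.finite(dir[, 1])
      if (any(bad)) dir[bad, ] <- 0
      new_a <- working_a - control$gamma * dir[, 1]
      new_c <- working_c - control$gamma * dir[, 2]
      update <- update + 1L
      prev_mean <- state$mean
      state <- update_average(state, c(new_a, new_c))
      working <- state$working
      working_a <- working[seq_len(prep$n_items)]
      working_c <- working[prep$n_items + seq_len(prep$n_items)]
      chg <- if (!is.null(prev_mean)) max(abs(state$mean - prev_mean)) else NA_real_
      tr_change[[update]] <- chg
      tr_epoch[[update]] <- epoch
      tr_subset[[update]] <- s
      if (!is.na(chg) && chg < control$tol && check_stability(state)) {
        converged <- TRUE
        stop_subset <- s
        break
      }
    }
  }
  final <- if (!is.null(state$mean)) state$mean else c(working_a, working_c)
  a <- final[seq_len(prep$n_items)]
  c <- final[prep$n_items + seq_len(prep$n_items)]
  n_updates <- update
  traj2 <- tibble::tibble(
    iteration = s1$n_iter + seq_len(n_updates), stage = "stage2",
    loglik = NA_real_, delta = NA_real_,
    max_change = unlist(tr_change), epoch = unlist(tr_epoch),
    subset = unlist(tr_subset))
  list(a = a, c = c, converged = converged, transitioned = TRUE,
       n_iter = s1$n_iter,
       delta_at_transition = s1$delta_at_transition,
       trajectory = dplyr::bind_rows(s1$trajectory, traj2),
       stage2 = list(n_updates = n_updates, n_epochs = epoch,
                     epoch_params = epoch_params, plan = plan,
                     stop_subset = if (converged) stop_subset else length(plan)))
}

finalize_fit <- function(res, prep, g, grid, control, method, elapsed) {
  est <- item_params(res$a, res$c, item = prep$items)
  final_counts <- full_e_step(prep, res$a, res$c, g)
  info <- NULL
  se_a <- se_c <- rep(NA_real_, prep$n_items)
  if (control$compute_se) {
    info <- if (method == "two_stage" && !is.null(res$stage2)) {
      xpd_two_stage(prep, res, g)
    } else {
      xpd_information(prep$pd, est, grid)
    }
    se <- tryCatch(se_from_information(info, n = 1),
                   error = function(e) {
                     warn(paste("Standard errors unavailable:",
                                conditionMessage(e)))
                     rep(NA_real_, 2 * prep$n_items)
                   })
    se_a <- se[seq(1, 2 * prep$n_items, by = 2)]
    se_c <- se[seq(2, 2 * prep$n_items, by = 2)]
  }
  est$se_a <- se_a
  est$se_c <- se_c
  structure(list(
    estimates = est, info = info, trajectory = res$trajectory,
    converged = res$converged, method = method, control = control,
    n_persons = prep$n_persons, n_items = prep$n_items,
    loglik = final_counts$loglik,
    stage2 = if (!is.null(res$stage2)) {
      list(transition_iteration = res$n_iter,
           delta_at_transition = res$delta_at_transition,
           n_updates = res$stage2$n_updates,
           n_epochs = res$stage2$n_epochs)
    },
    elapsed = elapsed), class = "em2pl")
}

# XPD for a two-stage fit: contributions from the final epoch's subsets at
# the working parameters each subset was visited with; subsets the stopped
# epoch never reached are finished at the final estimates.  Every person
# contributes exactly once.
xpd_two_stage <- function(prep, res, g) {
  s2 <- res$stage2
  M <- length(s2$plan)
  acc <- matrix(0, 2 * prep$n_items, 2 * prep$n_items)
  for (s in seq_len(M)) {
    par_s <- if (s <= s2$stop_subset && !is.null(s2$epoch_params[[s]])) {
      s2$epoch_params[[s]]
    } else {
      list(a = res$a, c = res$c, handle = s2$plan[[s]])
    }
    acc <- acc + stage2_xpd(prep, par_s$handle, par_s$a, par_s$c, g)
  }
  dimnames(acc) <- list(param_labels(prep$n_items),
                        param_labels(prep$n_items))
  structure(acc, kind = "xpd", n_eff = prep$n_persons)
}

#' @export
print.em2pl <- function(x, ...) {
  cat(sprintf("<em2pl fit: %s EM, %d items, %d persons>\n",
              ifelse(x$method == "two_stage", "two-stage", "standard"),
              x$n_items, x$n_persons))
  cat(sprintf("  log-likelihood %.3f | converged: %s\n",
              x$loglik, x$converged))
  if (!is.null(x$stage2)) {
    cat(sprintf(
      "  stage 2 after iteration %d (delta = %.3f): %d subset updates over %d epochs\n",
      x$stage2$transition_iteration, x$stage2$delta_at_transition,
      x$stage2$n_updates, x$stage2$n_epochs))
  }
  print(x$estimates, n = min(nrow(x$estimates), 10))
  invisible(x)
}
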