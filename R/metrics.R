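#' Recovery and standard-error evaluation metrics
#'
#' Replication-level summaries used by the simulation harness:
#' `param_bias()` is the mean of `estimate - truth` across replications,
#' `param_rmse()` the root mean squared deviation (always at least
#' `|bias|`; `rmse^2 - bias^2` equals the estimator variance computed with
#' denominator R).  `se_error_metrics()` applies the same two summaries to
#' estimated standard errors against a gold-standard value.
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param truth True (generating) parameter value.
#' @return A single number (`param_bias`, `param_rmse`) or a tibble with
#'   columns `bias` and `rmse` (`se_error_metrics`).
#' @examples
#' param_bias(c(1.0, 1.2), truth = 1.0)   # 0.1
#' param_rmse(c(0.9, 1.1), truth = 1.0)   # 0.1
#' @export
param_bias <- function(estimates, truth) {
  mean(estimates - truth)
}

#' @rdname param_bias
#' @export
param_rmse <- function(estimates, truth) {
  sqrt(mean((estimates - truth)^2))
}

#' @rdname param_bias
#' @param se_estimates Estimated standard errors across replications.
#' @param gold_se Gold-standard (Fisher expected-information) SE.
#' @export
se_error_metrics <- function(se_estimates, gold_se) {
  tibble::tibble(bias = param_bias(se_estimates, gold_se),
                 rmse = param_rmse(se_estimates, gold_se))
}

#' Percent change in mean time to convergence
#'
#' `(mean_modified - mean_full) / mean_full * 100`: negative values mean
#' the subset-based algorithm was faster than full-data standard EM.
#'
#' @param mean_modified Mean runtime of the two-stage algorithm (seconds).
#' @param mean_full Mean runtime of full-data standard EM (seconds).
#' @return Percent change (single number).
#' @examples
#' time_change_pct(387.89, 988.97)  # about -60.78
#' @export
time_change_pct <- function(mean_modified, mean_full) {
  if (any(mean_full <= 0)) abort("`mean_full` must be positive.")
  (mean_modified - mean_full) / mean_full * 100
}

#' Across-block bias for a repeated item
#'
#' In the multi-form design the same 20-item block appears five times in
#' the 100-item pool, so each true parameter has several estimated
#' instances.  Returns the mean deviation from truth across blocks together
#' with the minimum and maximum deviation.
#'
#' @param estimates Estimates of the same parameter, one per block.
#' @param truth True parameter value.
#' @return Tibble with columns `mean_bias`, `min_bias`, `max_bias`.
#' @export
block_bias <- function(estimates, truth) {
  d <- estimates - truth
  tibble::tibble(mean_bias = mean(d), min_bias = min(d), max_bias = max(d))
}

# ---------------------------------------------------------------------------
# study harness

# derive a bounded child seed from a root seed (R integers are 32-bit)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483629)
}

fit_elapsed <- function(data, method, control, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  fit <- fit_2pl(data, method = method, control = control, seed = seed)
  list(fit = fit, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Standard-error calibration study
#'
#' Repeatedly simulates 2PL data from a fixed item bank, fits each dataset
#' with the two-stage algorithm at several subset fractions (a fraction of
#' 1 plus `standard = TRUE` adds the full-data standard-EM reference), and
#' compares the XPD standard errors with the Fisher expected-information
#' gold standard computed at the true parameters.
#'
#' @param params True item parameters (default the packaged 12-item
#'   calibration bank).
#' @param reps Number of replications (default 200).
#' @param n_persons Persons per replication (default 60000).
#' @param fractions Stage-2 subset fractions to evaluate.
#' @param standard Also fit full-data standard EM as a reference condition.
#' @param control Base [em_control()]; `fraction` is overridden per
#'   condition.
#' @param seed Integer seed; replication r uses child seed `seed + r`.
#' @return List with `summary` (per condition x parameter: `gold_se`,
#'   `mean_se`, `bias`, `rmse`) and `gold` (the gold-standard SE table).
#' @export
se_calibration_study <- function(params = item_bank("se12"), reps = 200,
                                 n_persons = 60000,
                                 fractions = c(0.2, 0.3, 0.5, 1.0),
                                 standard = FALSE,
                                 control = em_control(), seed = 1) {
  p <- as_param_vectors(params)
  grid <- quadrature_grid(control$k, control$bound)
  gold <- se_from_information(fisher_information(params, grid),
                              n = n_persons)
  labels <- param_labels(length(p$a))
  conditions <- tibble::tibble(method = "two_stage", fraction = fractions)
  if (standard) {
    conditions <- dplyr::bind_rows(
      conditions, tibble::tibble(method = "standard", fraction = NA_real_))
  }
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    dat <- simulate_2pl(params, n_persons, seed = child_seed(seed, r))
    pd <- compress_patterns(dat)
    rows[[r]] <- purrr::pmap_dfr(conditions, function(method, fraction) {
      ctrl <- control
      if (!is.na(fraction)) ctrl$fraction <- fraction
      fit <- fit_2pl(pd, method = method, control = ctrl,
                     seed = child_seed(seed, 100000 + r))
      est <- fit$estimates
      tibble::tibble(rep = r, method = method, fraction = fraction,
                     parameter = labels,
                     estimate = as.vector(rbind(est$a, est$c)),
                     se = as.vector(rbind(est$se_a, est$se_c)))
    })
  }
  all <- dplyr::bind_rows(rows)
  truth <- setNames(as.vector(rbind(p$a, p$c)), labels)
  summary <- all |>
    dplyr::group_by(method, fraction, parameter) |>
    dplyr::summarise(
      gold_se = gold[[parameter[1]]],
      mean_est = mean(estimate),
      bias_est = param_bias(estimate, truth[[parameter[1]]]),
      rmse_est = param_rmse(estimate, truth[[parameter[1]]]),
      mean_se = mean(se),
      bias = param_bias(se, gold_se[1]),
      rmse = param_rmse(se, gold_se[1]),
      .groups = "drop")
  list(summary = summary, gold = gold, estimates = all)
}

#' Run one of the packaged simulation studies
#'
#' Desk-scale orchestration of the four study designs: (1) parameter
#' recovery and runtime across subset fractions, item counts and switching
#' thresholds; (2) standard-error calibration ([se_calibration_study()]);
#' (3) a single large multi-form planned-missingness calibration of a
#' 100-item pool; (4) robustness under testlet-induced multidimensionality.
#' Replication counts and sample sizes default to desk scale and are fully
#' configurable.
#'
#' @param study Study number, 1 to 4.
#' @param reps Replications per condition (defaults: 20, 200, 1, 20).
#' @param n_persons Persons per replication (defaults: 60000, 60000,
#'   100000, 60000).
#' @param fractions Subset fractions (study-specific defaults).
#' @param thresholds Switching thresholds (study 1/3).
#' @param items Item counts, subset of 18/36/54 (study 1).
#' @param testlet_vars Common testlet variances (study 4).
#' @param control Base [em_control()].
#' @param seed Root seed.
#' @return A list of tidy tibbles; always `results` (per condition x
#'   parameter) and `timing` (per condition), plus study-specific extras.
#' @export
run_study <- function(study, reps = NULL, n_persons = NULL, fractions = NULL,
                      thresholds = NULL, items = NULL, testlet_vars = NULL,
                      control = em_control(), seed = 1) {
  stopifnot(study %in% 1:4)
  switch(study,
         run_study1(reps %||% 20, n_persons %||% 60000,
                    fractions %||% c(0.1, 0.2, 0.3, 0.5),
                    thresholds %||% c(0.1, 0.5, 0.9),
                    items %||% c(18, 36, 54), control, seed),
         {
           out <- se_calibration_study(
             reps = reps %||% 200, n_persons = n_persons %||% 60000,
             fractions = fractions %||% c(0.1, 0.2, 0.3, 0.5, 1.0),
             standard = TRUE, control = control, seed = seed)
           list(results = out$summary, gold = out$gold)
         },
         run_study3(n_persons %||% 100000,
                    fractions %||% 0.2, thresholds %||% 0.9, control, seed),
         run_study4(reps %||% 20, n_persons %||% 60000,
                    fractions %||% c(0.2, 1.0),
                    testlet_vars %||% c(0.05, 0.2, 0.5, 1.0), control, seed))
}

study_fit_rows <- function(pd, truth_a, truth_c, method, ctrl, seed) {
  fr <- fit_elapsed(pd, method, ctrl, seed = seed)
  est <- fr$fit$estimates
  labels <- param_labels(length(truth_a))
  tibble::tibble(parameter = labels,
                 type = rep(c("a", "c"), length(truth_a)),
                 item = rep(seq_along(truth_a), each = 2),
                 truth = as.vector(rbind(truth_a, truth_c)),
                 estimate = as.vector(rbind(est$a, est$c)),
                 elapsed = fr$elapsed,
                 converged = fr$fit$converged)
}

#' Condition grid of the recovery/runtime study
#'
#' Crosses subset fractions, switching thresholds and item counts for the
#' two-stage algorithm, plus one full-data standard-EM baseline per item
#' count (at the defaults: 4 x 3 x 3 + 3 = 39 conditions).
#'
#' @inheritParams run_study
#' @return Tibble with columns `items`, `method`, `fraction`, `threshold`.
#' @export
study1_conditions <- function(fractions = c(0.1, 0.2, 0.3, 0.5),
                              thresholds = c(0.1, 0.5, 0.9),
                              items = c(18, 36, 54)) {
  dplyr::bind_rows(
    tidyr::expand_grid(items = items, method = "two_stage",
                       fraction = fractions, threshold = thresholds),
    tidyr::expand_grid(items = items, method = "standard",
                       fraction = NA_real_, threshold = NA_real_))
}

run_study1 <- function(reps, n_persons, fractions, thresholds, items,
                       control, seed) {
  banks <- list(`18` = item_bank("grid18"), `36` = item_bank("grid36"),
                `54` = item_bank("grid54"))
  conditions <- study1_conditions(fractions, thresholds, items)
  rows <- purrr::map_dfr(seq_len(reps), function(r) {
    purrr::map_dfr(items, function(it) {
      bank <- banks[[as.character(it)]]
      dat <- simulate_2pl(bank, n_persons,
                          seed = child_seed(seed, 97 * r + it))
      pd <- compress_patterns(dat)
      cond_it <- dplyr::filter(conditions, items == it)
      purrr::pmap_dfr(cond_it, function(items, method, fraction, threshold) {
        ctrl <- control
        if (!is.na(fraction)) ctrl$fraction <- fraction
        if (!is.na(threshold)) ctrl$threshold <- threshold
        out <- study_fit_rows(pd, bank$a, bank$c, method, ctrl,
                              seed = child_seed(seed, 200000 + 7 * r + it))
        dplyr::mutate(out, rep = r, items = items, method = method,
                      fraction = fraction, threshold = threshold)
      })
    })
  })
  results <- rows |>
    dplyr::group_by(items, method, fraction, threshold, parameter, type,
                    item) |>
    dplyr::summarise(truth = truth[1],
                     mean_est = mean(estimate), sd_est = stats::sd(estimate),
                     bias = param_bias(estimate, truth[1]),
                     rmse = param_rmse(estimate, truth[1]),
                     .groups = "drop")
  timing <- summarise_timing(rows)
  list(results = results, timing = timing, replications = rows)
}

summarise_timing <- function(rows) {
  per_fit <- dplyr::distinct(
    rows, dplyr::across(dplyr::any_of(
      c("items", "method", "fraction", "threshold", "rep", "elapsed"))))
  tm <- per_fit |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("items", "method", "fraction", "threshold")))) |>
    dplyr::summarise(mean_time = mean(elapsed), sd_time = stats::sd(elapsed),
                     .groups = "drop")
  base <- dplyr::filter(tm, method == "standard")
  if (nrow(base) > 0) {
    base_key <- if ("items" %in% names(base)) base$items else rep(1, nrow(base))
    ref <- setNames(base$mean_time, base_key)
    tm$change_pct <- ifelse(
      tm$method == "standard", 0,
      time_change_pct(tm$mean_time,
                      ref[as.character(if ("items" %in% names(tm)) tm$items
                                       else rep(1, nrow(tm)))]))
  }
  tm
}

run_study3 <- function(n_persons, fractions, thresholds, control, seed) {
  pool <- item_pool100()
  dat <- simulate_2pl(pool, n_persons, seed = seed)
  design <- build_form_design(n_persons, seed = seed + 1L)
  dat <- apply_form_design(dat, design)
  pd <- compress_patterns(dat)
  conditions <- dplyr::bind_rows(
    tidyr::expand_grid(method = "two_stage", fraction = fractions,
                       threshold = thresholds),
    tibble::tibble(method = "standard", fraction = NA_real_,
                   threshold = NA_real_))
  rows <- purrr::pmap_dfr(conditions, function(method, fraction, threshold) {
    ctrl <- control
    if (!is.na(fraction)) ctrl$fraction <- fraction
    if (!is.na(threshold)) ctrl$threshold <- threshold
    out <- study_fit_rows(pd, pool$a, pool$c, method, ctrl,
                          seed = seed + 11L)
    dplyr::mutate(out, method = method, fraction = fraction,
                  threshold = threshold,
                  block = pool$block[item], pool_item = pool$pool_item[item])
  })
  # across-block bias for each of the 20 repeated pool parameters
  blockwise <- rows |>
    dplyr::group_by(method, fraction, threshold, type, pool_item) |>
    dplyr::summarise(block_bias(estimate, truth[1]), .groups = "drop")
  list(results = blockwise, timing = summarise_timing(rows),
       replications = rows)
}

run_study4 <- function(reps, n_persons, fractions, testlet_vars, control,
                       seed) {
  bank <- item_bank("testlet30")
  conditions <- dplyr::bind_rows(
    tidyr::expand_grid(method = "two_stage", fraction = fractions,
                       testlet_var = testlet_vars),
    tidyr::expand_grid(method = "standard", fraction = NA_real_,
                       testlet_var = testlet_vars))
  rows <- purrr::map_dfr(seq_len(reps), function(r) {
    purrr::map_dfr(testlet_vars, function(tv) {
      dat <- simulate_testlet_2pl(bank, n_persons, testlet_var = tv,
                                  seed = child_seed(seed, 131 * r + round(1000 * tv)))
      pd <- compress_patterns(dat)
      cond_tv <- dplyr::filter(conditions, testlet_var == tv)
      purrr::pmap_dfr(cond_tv, function(method, fraction, testlet_var) {
        ctrl <- control
        if (!is.na(fraction)) ctrl$fraction <- fraction
        out <- study_fit_rows(pd, bank$a, bank$c, method, ctrl,
                              seed = child_seed(seed, 300000 + r))
        dplyr::mutate(out, rep = r, method = method, fraction = fraction,
                      testlet_var = testlet_var)
      })
    })
  })
  results <- rows |>
    dplyr::group_by(method, fraction, testlet_var, parameter, type, item) |>
    dplyr::summarise(truth = truth[1],
                     bias = param_bias(estimate, truth[1]),
                     rmse = param_rmse(estimate, truth[1]),
                     .groups = "drop")
  list(results = results, timing = summarise_timing(rows),
       replications = rows)
}
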