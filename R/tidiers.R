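#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a 2PL fit
#'
#' @param x An `em2pl` fit from [fit_2pl()].
#' @param ... Unused.
#' @return One row per item: `item`, `a`, `se_a`, `c`, `se_c`, `b`
#'   (difficulty `-c/a`).
#' @export
tidy.em2pl <- function(x, ...) {
  dplyr::select(x$estimates, item, a, se_a, c, se_c, b)
}

#' @rdname tidy.em2pl
#' @return `glance()`: a one-row tibble with fit-level summaries
#'   (`n_persons`, `n_items`, `method`, `converged`, `loglik`, iteration
#'   and Stage-2 bookkeeping, `elapsed` seconds).
#' @export
glance.em2pl <- function(x, ...) {
  tibble::tibble(
    n_persons = x$n_persons, n_items = x$n_items, method = x$method,
    converged = x$converged, loglik = x$loglik,
    n_stage1 = sum(x$trajectory$stage == "stage1"),
    transition_iteration = x$stage2$transition_iteration %||% NA_integer_,
    delta_at_transition = x$stage2$delta_at_transition %||% NA_real_,
    n_stage2_updates = x$stage2$n_updates %||% 0L,
    n_stage2_epochs = x$stage2$n_epochs %||% 0L,
    elapsed = x$elapsed)
}

#' Plot an EM estimation trajectory
#'
#' Shows the largest absolute parameter change per update on a log scale,
#' colored by stage.  The hump-shaped Stage-1 decline, the switch point,
#' and the Stage-2 noise-ball behaviour of the averaged iterates are all
#' visible in this view.
#'
#' @param object An `em2pl` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.em2pl <- function(object, ...) {
  tr <- dplyr::filter(object$trajectory, !is.na(max_change), max_change > 0)
  ggplot2::ggplot(tr, ggplot2::aes(iteration, max_change, colour = stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "update", y = "max |parameter change|",
                  colour = NULL,
                  title = sprintf("%s EM trajectory",
                                  ifelse(object$method == "two_stage",
                                         "Two-stage", "Standard"))) +
    ggplot2::theme_minimal()
}

#' Plot item characteristic curves
#'
#' @param params Item parameter table (columns `a`, `c`), e.g.
#'   [item_bank()] or `tidy()` of a fit.
#' @param theta_range Latent-trait range to draw.
#' @return A ggplot object with one logistic curve per item.
#' @export
plot_item_curves <- function(params, theta_range = c(-4, 4)) {
  p <- as_param_vectors(params)
  curves <- tidyr::expand_grid(
    item = factor(p$item, levels = p$item),
    theta = seq(theta_range[1], theta_range[2], length.out = 101))
  idx <- match(curves$item, factor(p$item, levels = p$item))
  curves$prob <- prob_2pl(p$a[idx], p$c[idx], curves$theta)
  ggplot2::ggplot(curves,
                  ggplot2::aes(theta, prob, group = item, colour = item)) +
    ggplot2::geom_line(show.legend = length(p$a) <= 12) +
    ggplot2::labs(x = "latent trait", y = "P(correct)") +
    ggplot2::theme_minimal()
}
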