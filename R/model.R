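#' Item parameter tables
#'
#' A 2PL item is described by its slope (discrimination) `a` and intercept
#' `c`, on the logit scale: the probability of a 1-response at latent trait
#' `theta` is `plogis(a * theta + c)`.  The difficulty `b = -c / a` is the
#' latent location where that probability is 0.5.
#'
#' @param a Numeric vector of slopes.
#' @param c Numeric vector of intercepts (recycled against `a`).
#' @param item Optional item labels (default `1:I`).
#' @return A tibble with columns `item`, `a`, `c` and derived `b`
#'   (`NA` where `a == 0`).
#' @examples
#' item_params(a = c(1, 2), c = c(0, -1))
#' @export
item_params <- function(a, c = 0, item = NULL) {
  n <- max(length(a), length(c))
  a <- rep_len(as.numeric(a), n)
  c <- rep_len(as.numeric(c), n)
  if (any(!is.finite(a)) || any(!is.finite(c))) {
    abort("Item parameters must be finite.")
  }
  if (n < 1) abort("At least one item is required.")
  item <- item %||% seq_len(n)
  tibble::tibble(item = item, a = a, c = c,
                 b = ifelse(a == 0, NA_real_, -c / a))
}

# normalize user input (tibble with a/c columns, or list) to plain vectors
as_param_vectors <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(all(c("a", "c") %in% names(params)))
    list(a = as.numeric(params$a), c = as.numeric(params$c),
         item = params$item %||% seq_len(nrow(params)))
  } else if (is.list(params) && all(c("a", "c") %in% names(params))) {
    list(a = as.numeric(params$a), c = as.numeric(params$c),
         item = params$item %||% seq_along(params$a))
  } else {
    abort("`params` must be a data frame (or list) with columns `a` and `c`.")
  }
}

#' 2PL response probability
#'
#' Probability of a 1-response under the two-parameter logistic model,
#' `P(y = 1 | theta) = 1 / (1 + exp(-(a * theta + c)))`.  Vectorized over
#' all arguments; saturates gracefully at extreme logits.
#'
#' @param a Slope (discrimination).
#' @param c Intercept.
#' @param theta Latent trait value(s).
#' @return Probabilities in (0, 1) (0/1 only at infinite logits).
#' @examples
#' prob_2pl(a = 1, c = 0, theta = 0)       # 0.5
#' prob_2pl(a = 3.17, c = -9.46, theta = 2.99)
#' @export
prob_2pl <- function(a, c, theta) {
  plogis(a * theta + c)
}

#' Item difficulty from slope and intercept
#'
#' The difficulty parameterization satisfies `c = -a * b`, so `b = -c / a`.
#' Undefined (error) for zero slopes.
#'
#' @inheritParams prob_2pl
#' @return Numeric vector of difficulties.
#' @examples
#' item_difficulty(a = 0.68, c = 1.60)  # -2.35 at 2 decimals
#' @export
item_difficulty <- function(a, c) {
  if (any(a == 0)) abort("Difficulty b = -c/a is undefined for zero slopes.")
  -c / a
}
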