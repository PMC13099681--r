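#' Simulate binary responses from a unidimensional 2PL model
#'
#' Draws person abilities `theta ~ N(0, 1)` and responses
#' `y_ip ~ Bernoulli(plogis(a_i * theta_p + c_i))`, independently across
#' items given theta.
#'
#' @param params Item parameter table (columns `a`, `c`).
#' @param n Number of persons.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return Tibble of 0/1 integer responses, persons in rows, one column per
#'   item (named from `params$item` when character, else `item_1` ...).
#'   The latent abilities are attached as attribute `"theta"`.
#' @examples
#' simulate_2pl(item_params(a = c(1, 2), c = c(0, -1)), n = 5, seed = 1)
#' @export
simulate_2pl <- function(params, n, seed = NULL) {
  p <- as_param_vectors(params)
  if (n < 1) abort("`n` must be at least 1.")
  draw <- function() {
    theta <- rnorm(n)
    pr <- plogis(outer(theta, p$a) + rep(p$c, each = n))
    y <- matrix(as.integer(runif(n * length(p$a)) < pr), n)
    colnames(y) <- item_col_names(p)
    out <- tibble::as_tibble(y)
    attr(out, "theta") <- theta
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

item_col_names <- function(p) {
  if (is.character(p$item)) p$item else paste0("item_", p$item)
}

#' Sample true item parameters from the 3 x 3 level grid
#'
#' Slopes (A) and difficulties (B) are drawn uniformly within a 3 x 3 grid
#' of level cells — A: low \[0.50, 1.50), medium \[1.50, 2.50),
#' high \[2.50, 3.50\]; B: low \[-3.00, -1.50), medium \[-1.50, 1.50),
#' high \[1.50, 3.00\] — with an equal number of items per cell.
#' Intercepts follow as `C = -A * B`, spanning \[-10.50, 10.50\], and get
#' level labels low/medium/high from cutoffs at -3.75 and 3.75.
#'
#' @param n_items Number of items; must be a multiple of 9.
#' @param seed Optional integer seed.
#' @return Tibble with columns `item`, `a`, `b`, `c`, `level_a`, `level_b`,
#'   `level_c`.
#' @examples
#' sample_true_params(18, seed = 1)
#' @export
sample_true_params <- function(n_items, seed = NULL) {
  if (n_items %% 9 != 0) abort("`n_items` must be a multiple of 9 (3 x 3 grid).")
  per_cell <- n_items / 9
  a_ranges <- list(low = c(0.50, 1.50), medium = c(1.50, 2.50),
                   high = c(2.50, 3.50))
  b_ranges <- list(low = c(-3.00, -1.50), medium = c(-1.50, 1.50),
                   high = c(1.50, 3.00))
  draw <- function() {
    cells <- tidyr::expand_grid(level_a = names(a_ranges),
                                level_b = names(b_ranges))
    out <- purrr::pmap_dfr(cells, function(level_a, level_b) {
      a_v <- runif(per_cell, a_ranges[[level_a]][1], a_ranges[[level_a]][2])
      b_v <- runif(per_cell, b_ranges[[level_b]][1], b_ranges[[level_b]][2])
      tibble::tibble(level_a = level_a, level_b = level_b, a = a_v, b = b_v)
    })
    out$c <- -out$a * out$b
    out$level_c <- cut(out$c, c(-10.5, -3.75, 3.75, 10.5),
                       labels = c("low", "medium", "high"),
                       include.lowest = TRUE)
    out$level_c <- as.character(out$level_c)
    dplyr::select(dplyr::mutate(out, item = dplyr::row_number()),
                  item, a, b, c, level_a, level_b, level_c)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Multi-form planned-missingness design
#'
#' Emulates a large-scale testing scenario: a 100-item pool is split into
#' five 20-item blocks; the ten possible unordered block pairs define ten
#' 40-item forms; each person is assigned to one form uniformly at random
#' and the 60 items outside their form are missing by design.
#'
#' @param n_persons Number of persons (at least 10).
#' @param seed Optional integer seed.
#' @return A `form_design` list: `blocks` (item -> block, length 100),
#'   `forms` (10 x 2 matrix of block pairs), `assignment` (person -> form)
#'   and `observed` (n x 100 logical mask).
#' @export
build_form_design <- function(n_persons, seed = NULL) {
  if (n_persons < 10) abort("`n_persons` must be at least 10.")
  blocks <- rep(1:5, each = 20)
  forms <- t(combn(5, 2))               # 10 forms = all unordered pairs
  draw <- function() {
    assignment <- sample.int(nrow(forms), n_persons, replace = TRUE)
    observed <- matrix(FALSE, n_persons, 100)
    for (fm in seq_len(nrow(forms))) {
      rows <- assignment == fm
      cols <- blocks %in% forms[fm, ]
      observed[rows, cols] <- TRUE
    }
    structure(list(blocks = blocks, forms = forms, assignment = assignment,
                   observed = observed), class = "form_design")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.form_design <- function(x, ...) {
  cat(sprintf("<form_design: %d persons over %d forms (%d items, %d blocks)>\n",
              length(x$assignment), nrow(x$forms), length(x$blocks),
              max(x$blocks)))
  invisible(x)
}

#' Apply a form design's missingness mask to a response table
#'
#' @param responses Person-by-item table with as many columns as the design
#'   has pool items.
#' @param design A `form_design` from [build_form_design()].
#' @return The responses with items outside each person's form set to `NA`.
#' @export
apply_form_design <- function(responses, design) {
  m <- as.matrix(responses)
  stopifnot(ncol(m) == ncol(design$observed),
            nrow(m) == nrow(design$observed))
  m[!design$observed] <- NA
  out <- tibble::as_tibble(m)
  attr(out, "theta") <- attr(responses, "theta", exact = TRUE)
  out
}

#' Simulate from a testlet 2PL model (misspecification generator)
#'
#' Generates data from a multidimensional model with a general latent trait
#' plus uncorrelated testlet-specific traits: the linear predictor for item
#' i of person p is `a_i * (theta_p + u_{t(i),p}) + c_i`, with
#' `theta ~ N(0, 1)` and `u_t ~ N(0, testlet_var)` — each item loads
#' equally on the general and its own testlet dimension.  Fitting a
#' unidimensional 2PL to such data probes robustness to local dependence;
#' `testlet_var = 0` reproduces [simulate_2pl()] exactly (same seed, same
#' matrix).
#'
#' @param params Item parameter table (columns `a`, `c`; optional `testlet`
#'   membership column).
#' @param n Number of persons.
#' @param testlet_var Common testlet variance (>= 0).
#' @param testlet Integer membership vector overriding `params$testlet`;
#'   default: three consecutive equal-size testlets.
#' @param seed Optional integer seed.
#' @return Tibble of 0/1 responses with attributes `"theta"` and
#'   `"testlet"`.
#' @export
simulate_testlet_2pl <- function(params, n, testlet_var, testlet = NULL,
                                 seed = NULL) {
  p <- as_param_vectors(params)
  I <- length(p$a)
  testlet <- testlet %||%
    (if (is.data.frame(params) && "testlet" %in% names(params)) {
      params$testlet
    } else {
      rep(seq_len(3), each = ceiling(I / 3))[seq_len(I)]
    })
  if (length(testlet) != I || anyNA(testlet)) {
    abort("`testlet` membership must cover every item.")
  }
  if (testlet_var < 0) abort("`testlet_var` must be non-negative.")
  draw <- function() {
    theta <- rnorm(n)
    z <- outer(theta, p$a) + rep(p$c, each = n)
    if (testlet_var > 0) {
      u <- matrix(rnorm(n * length(unique(testlet)), sd = sqrt(testlet_var)),
                  n)
      z <- z + u[, match(testlet, sort(unique(testlet)))] *
        rep(p$a, each = n)
    }
    y <- matrix(as.integer(runif(n * I) < plogis(z)), n)
    colnames(y) <- item_col_names(p)
    out <- tibble::as_tibble(y)
    attr(out, "theta") <- theta
    attr(out, "testlet") <- testlet
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
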