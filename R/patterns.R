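#' Coerce and validate a person-by-item response table
#'
#' Accepts a matrix or data frame with persons in rows and items in columns.
#' Cells must be 0, 1 or `NA` (planned missingness).  Offending cells are
#' reported by row and column.  Items with zero observed variance (all-0 or
#' all-1 among observed responses) are rejected because their maximum
#' likelihood estimates diverge; rows with no observed responses are
#' likewise rejected.
#'
#' @param data Matrix or data frame of 0/1/`NA` responses.
#' @param check_variance Reject zero-variance items (default `TRUE`).
#' @return A numeric matrix with item names as column names.
#' @export
as_response_matrix <- function(data, check_variance = TRUE) {
  m <- as.matrix(data)
  if (length(m) == 0) abort("Response data is empty.")
  storage.mode(m) <- "numeric"
  bad <- which(!(is.na(m) | m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-binary response at row %d, column '%s' (value %s).",
      bad[1, 1], colnames(m)[bad[1, 2]] %||% as.character(bad[1, 2]),
      format(m[bad[1, , drop = FALSE]])))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("item_", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("Duplicate item id '%s'.",
                  colnames(m)[duplicated(colnames(m))][1]))
  }
  all_miss <- rowSums(!is.na(m)) == 0
  if (any(all_miss)) {
    abort(sprintf("Row %d has no observed responses.", which(all_miss)[1]))
  }
  if (check_variance) {
    mn <- colMeans(m, na.rm = TRUE)
    flat <- which(mn == 0 | mn == 1)
    if (length(flat) > 0) {
      abort(sprintf(
        "Item(s) with zero observed variance (all 0 or all 1): %s. Their MLEs diverge; drop them before fitting.",
        paste(colnames(m)[flat], collapse = ", ")))
    }
  }
  m
}

#' Compress a response matrix to unique patterns and frequencies
#'
#' The marginal likelihood depends on the data only through the distinct
#' response patterns and their frequencies, so all estimation routines work
#' on this compressed form.  Patterns that differ only in their missingness
#' mask are distinct.  Rows are ordered lexicographically (missing sorts
#' after 0/1) so the result is independent of person order.
#'
#' @param data Response matrix or data frame (0/1/`NA` cells).
#' @param check_variance Passed to [as_response_matrix()].
#' @return A `pattern_data` object: list with `U` (R x I, missing coded 0),
#'   `O` (R x I observation mask), `f` (frequencies), `n_persons`,
#'   `row_index` (person to pattern-row map) and `items`.
#' @examples
#' compress_patterns(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 0, 1)))
#' @export
compress_patterns <- function(data, check_variance = FALSE) {
  m <- as_response_matrix(data, check_variance = check_variance)
  key <- pattern_keys(m)
  lev <- sort(unique(key), method = "radix")
  idx <- match(key, lev)
  first <- match(lev, key)
  U <- m[first, , drop = FALSE]
  f <- tabulate(idx, nbins = length(lev))
  new_pattern_data(U, f, n_persons = nrow(m), row_index = idx,
                   items = colnames(m))
}

pattern_keys <- function(m) {
  ch <- m
  ch[is.na(ch)] <- 2  # missing sorts after 0/1
  storage.mode(ch) <- "integer"
  do.call(paste0, as.data.frame(ch))
}

new_pattern_data <- function(U, f, n_persons, row_index = NULL, items = NULL) {
  O <- 1 - is.na(U)
  U0 <- U
  U0[is.na(U0)] <- 0
  structure(list(U = U0, O = O, f = as.numeric(f), n_persons = n_persons,
                 row_index = row_index,
                 items = items %||% colnames(U) %||%
                   paste0("item_", seq_len(ncol(U)))),
            class = "pattern_data")
}

#' @export
print.pattern_data <- function(x, ...) {
  cat(sprintf("<pattern_data: %d unique patterns, %d items, %d persons>\n",
              nrow(x$U), ncol(x$U), x$n_persons))
  invisible(x)
}

#' Pattern summary as a tibble
#'
#' @param x A `pattern_data` object.
#' @param ... Unused.
#' @return Tibble with one row per pattern: `pattern` (string, `N` for
#'   missing) and `f`.
#' @export
tidy.pattern_data <- function(x, ...) {
  ch <- matrix(as.character(x$U), nrow(x$U))
  ch[x$O == 0] <- "N"
  tibble::tibble(pattern = do.call(paste0, as.data.frame(ch)), f = x$f)
}

#' Shuffle persons into disjoint subsets
#'
#' Builds the Stage-2 partition plan: person indices are shuffled, then cut
#' into consecutive blocks of size `floor(fraction * n_persons)`; any
#' remainder forms one final smaller subset.  For example 10,000 persons at
#' 5% give 20 subsets of 500.
#'
#' @param n_persons Total number of persons P.
#' @param fraction Subset size as a fraction of P, in (0, 1].
#' @param seed Optional integer seed; when supplied the shuffle is drawn
#'   from a local RNG stream and the caller's RNG state is untouched.
#' @return A `subset_plan`: list of disjoint index vectors covering
#'   `1:n_persons`, with attributes `fraction` and `subset_size`.
#' @examples
#' lengths(make_subsets(10, fraction = 0.3, seed = 1))  # 3 3 3 1
#' @export
make_subsets <- function(n_persons, fraction, seed = NULL) {
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1].")
  }
  if (n_persons < 1) abort("`n_persons` must be positive.")
  size <- max(1L, as.integer(floor(fraction * n_persons)))
  perm <- if (is.null(seed)) {
    sample.int(n_persons)
  } else {
    withr::with_seed(seed, sample.int(n_persons))
  }
  n_full <- n_persons %/% size
  sizes <- rep(size, n_full)
  if (n_persons - n_full * size > 0) sizes <- c(sizes, n_persons - n_full * size)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  plan <- purrr::map2(starts, ends, function(s, e) perm[s:e])
  structure(plan, fraction = fraction, subset_size = size,
            class = c("subset_plan", "list"))
}

#' Pattern data for one subset of a partition plan
#'
#' @param data Response matrix/data frame, or the `pattern_data` from
#'   [compress_patterns()] on the full matrix (faster when reused).
#' @param plan A `subset_plan` from [make_subsets()].
#' @param s Subset index (1-based).
#' @return `pattern_data` for the persons in subset `s`.
#' @export
subset_patterns <- function(data, plan, s) {
  if (s < 1 || s > length(plan)) {
    abort(sprintf("Subset index %d out of range 1..%d.", s, length(plan)))
  }
  idx <- plan[[s]]
  if (inherits(data, "pattern_data")) {
    if (is.null(data$row_index)) {
      abort("`pattern_data` lacks the person-to-pattern map; recompress the raw matrix.")
    }
    f_s <- tabulate(data$row_index[idx], nbins = length(data$f))
    keep <- f_s > 0
    structure(list(U = data$U[keep, , drop = FALSE],
                   O = data$O[keep, , drop = FALSE],
                   f = as.numeric(f_s[keep]), n_persons = length(idx),
                   row_index = NULL, items = data$items),
              class = "pattern_data")
  } else {
    m <- as_response_matrix(data, check_variance = FALSE)
    compress_patterns(m[idx, , drop = FALSE])
  }
}

# full-enumeration person encoding for compact, fully observed tests:
# pattern id of person p is 1 + sum_i y_pi * 2^(i-1)
enum_encoding <- function(m, limit = 13L) {
  if (ncol(m) > limit || anyNA(m)) return(NULL)
  id <- as.integer(m %*% 2^(seq_len(ncol(m)) - 1)) + 1L
  list(id = id, n_patterns = 2L^ncol(m))
}

# 2^I x I matrix of all fully observed patterns in enum order (bit i -> item i)
enum_pattern_matrix <- function(n_items) {
  R <- 2L^n_items
  U <- matrix(0, R, n_items)
  r <- 0:(R - 1L)
  for (i in seq_len(n_items)) U[, i] <- r %/% 2L^(i - 1L) %% 2L
  U
}
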