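#' Packaged item banks
#'
#' Fixed item parameter tables shipped with the package and used as the
#' true values of its simulation studies:
#'
#' * `"grid18"`, `"grid36"`, `"grid54"` — grid-sampled banks (slope,
#'   difficulty and intercept with `c = -a * b`; the 18-item bank carries
#'   low/medium/high level labels).
#' * `"se12"` — the 12-item bank used for standard-error calibration; its
#'   difficulties span -2.35 to 2.29.
#' * `"pool20"` — the 20-item block repeated five times to form the
#'   100-item pool of the multi-form design; difficulties span -1.26 to
#'   1.59.
#' * `"testlet30"` — the 30-item bank (three testlets of ten items) for the
#'   dimensionality robustness study.
#'
#' @param name One of the bank names above.
#' @return A tibble with at least columns `item`, `a`, `c`.
#' @examples
#' item_bank("se12")
#' @export
item_bank <- function(name = c("grid18", "grid36", "grid54", "se12",
                               "pool20", "testlet30")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("bank_", name, ".csv"),
                      package = "emirt", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (!"c" %in% names(out)) out$c <- -out$a * out$b
  out
}

#' The 100-item pool of the multi-form design
#'
#' Five 20-item blocks sharing the `"pool20"` parameter values (the same
#' block repeated, but estimated as 100 distinct items, which is what makes
#' across-block bias summaries possible).
#'
#' @return Tibble with columns `item` (1..100), `block` (1..5),
#'   `pool_item` (1..20 within block), `a`, `c`.
#' @export
item_pool100 <- function() {
  block <- item_bank("pool20")
  out <- tidyr::expand_grid(block_id = 1:5, pool_item = block$item)
  out <- dplyr::left_join(out, dplyr::rename(block, pool_item = item),
                          by = "pool_item")
  dplyr::transmute(out, item = dplyr::row_number(), block = block_id,
                   pool_item = pool_item, a = a, c = c)
}
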