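#' Read a person-by-item response file
#'
#' Reads a CSV/TSV file with a header row of item ids and one row per
#' person; cells must be 0, 1 or the missing token.  Validation (non-binary
#' cells, duplicate item ids, zero-variance items, all-missing rows) is the
#' same as [as_response_matrix()] and failures name the offending
#' row/column.
#'
#' @param path File path (delimiter inferred from the extension: `.tsv` is
#'   tab, anything else comma).
#' @param missing Missing-data token (default `"NA"`).
#' @param check_variance Reject zero-variance items (default `TRUE`).
#' @return Numeric response matrix with item-id column names.
#' @export
read_responses <- function(path, missing = "NA", check_variance = TRUE) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, na = missing,
                          col_types = readr::cols(.default = readr::col_double()),
                          progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Non-numeric response at row %d, column %d of '%s'.",
                  prob$row[1], prob$col[1], path))
  }
  as_response_matrix(df, check_variance = check_variance)
}

#' Write fit artifacts
#'
#' `write_parameters()` writes the per-item estimate table
#' (`item, a, c, b, se_a, se_c`), `write_trajectory()` the per-iteration
#' log (`iteration, stage, loglik, delta, max_change, epoch, subset`), and
#' `write_run_metadata()` a JSON file with the configuration, seed,
#' convergence flag and stage-transition record — enough to reproduce the
#' run exactly.
#'
#' @param fit An `em2pl` fit.
#' @param path Output file path.
#' @param seed The seed the run was started with (metadata only).
#' @return The path, invisibly.
#' @export
write_parameters <- function(fit, path) {
  readr::write_csv(dplyr::select(fit$estimates, item, a, c, b, se_a, se_c),
                   path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
write_trajectory <- function(fit, path) {
  readr::write_csv(fit$trajectory, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
write_run_metadata <- function(fit, path, seed = NULL) {
  meta <- list(
    package_version = as.character(utils::packageVersion("emirt")),
    method = fit$method,
    control = unclass(fit$control),
    seed = seed,
    n_persons = fit$n_persons,
    n_items = fit$n_items,
    converged = fit$converged,
    loglik = fit$loglik,
    stage2 = fit$stage2,
    elapsed = fit$elapsed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_parameters
#' @param params Item parameter table to write (e.g. a bank or `tidy()`
#'   output).
#' @export
write_item_params <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}
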