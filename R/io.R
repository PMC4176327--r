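#' Write a table of records to CSV or JSON
#'
#' CSV output keeps the data frame's column order and rounds floating-point
#' columns to six significant digits; JSON mirrors the field names exactly.
#' An empty record set is an error, not an empty file.
#'
#' @param records non-empty data frame.
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame")
  if (format == "csv") {
    out <- records
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Machine-readable provenance header for a run summary
#'
#' @param seed RNG seed of the run (NA for deterministic runs).
#' @param params optional \code{clock_params} whose digest to record.
#' @return List with package version, seed and parameter hash, suitable for
#'   embedding in a JSON summary.
#' @export
run_provenance <- function(seed = NA, params = NULL) {
  list(package = "loopclock",
       version = as.character(utils::packageVersion("loopclock")),
       seed = if (is.na(seed)) NULL else as.integer(seed),
       params_hash = if (is.null(params)) NULL else params_hash(params))
}

#' Write a run summary with provenance to JSON
#'
#' @param results named list of results (scalars, vectors, data frames).
#' @param path output path.
#' @param seed,params forwarded to [run_provenance()].
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(results, path, seed = NA, params = NULL) {
  stopifnot(is.list(results), length(results) > 0)
  out <- c(list(provenance = run_provenance(seed, params)), results)
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' Read a (time, value) trace from CSV
#'
#' @param path CSV with columns \code{time} and \code{value}.
#' @return Data frame with those two columns.
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    stop("trace CSV needs columns 'time' and 'value'")
  d[, c("time", "value")]
}
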