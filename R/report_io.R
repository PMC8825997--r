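REPORT_SCHEMA_VERSION <- "1.0"

#' Write an analysis report to TSV or JSON
#'
#' TSV output holds the flat record table (suitable for spreadsheets);
#' JSON output additionally carries the summary counts, the tolerance used
#' and a `schema_version` field. Numeric values are written in full
#' precision so that a write/read cycle reproduces the records exactly.
#'
#' @param report A `derep_report`, or any data frame of result records.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`; default inferred from the extension.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  format <- match.arg(format, c("tsv", "json"))
  tab <- if (inherits(report, "derep_report")) report$table else
    tibble::as_tibble(report)
  if (format == "tsv") {
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    payload <- list(
      schema_version = REPORT_SCHEMA_VERSION,
      type = if (inherits(report, "derep_report")) "dereplication" else "table",
      summary = if (inherits(report, "derep_report")) report$summary else NULL,
      tol_ppm = if (inherits(report, "derep_report")) report$tol_ppm else NULL,
      records = tab
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report file path.
#' @param format `"tsv"` or `"json"`; default inferred from the extension.
#' @return For TSV, the record tibble. For JSON dereplication reports, a
#'   `derep_report`; for other JSON reports, the record tibble.
#' @export
read_report <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    return(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  records <- tibble::as_tibble(payload$records)
  if (identical(payload$type, "dereplication")) {
    report <- list(
      table = records,
      summary = payload$summary,
      tol_ppm = payload$tol_ppm
    )
    class(report) <- "derep_report"
    return(report)
  }
  records
}
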