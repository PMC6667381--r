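# Shared tabular I/O: schema-validated CSV input, CSV/JSON report output.
# CSV dialect: header row, period decimal separator, UTF-8.

#' Read and validate a CSV table against a schema
#'
#' Errors are structured and name the offending row and column. A decimal
#' comma in a numeric cell is rejected with explicit guidance, since it is
#' the most common locale accident.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"` or `"character"`).
#' @return data frame with the schema's columns coerced to their types
#'   (extra columns are kept as character).
#' @export
read_table <- function(path, schema) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_schema(sprintf("input file not found: %s", path))
  }
  raw <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             strip.white = TRUE, check.names = FALSE),
    error = function(e) stop_schema(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  if (nrow(raw) == 0L) stop_schema(sprintf("empty table: %s", path))
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop_schema(sprintf("%s: missing required column(s): %s",
                        path, paste(missing_cols, collapse = ", ")))
  }
  for (col in names(schema)) {
    if (schema[[col]] != "numeric") next
    cell <- raw[[col]]
    empty_as_na <- cell == "" | toupper(cell) == "NA"
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- is.na(parsed) & !empty_as_na
    if (any(bad)) {
      row <- which(bad)[1L]
      hint <- if (grepl("^-?[0-9]+,[0-9]+$", cell[row]))
        " (decimal comma? use a period as the decimal separator)" else ""
      stop_schema(sprintf("%s: non-numeric value '%s' in column '%s', row %d%s",
                          path, cell[row], col, row, hint))
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Write an analysis report
#'
#' JSON reports keep full float precision and add display-rounded twins
#' (suffix `_display`, 2 decimals) for the per-Gy/ratio printing convention;
#' field order is stable. CSV reports write the fields as columns.
#'
#' @param results named list (or single-row data frame) of scalar fields,
#'   or a data frame for CSV output.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @param display_digits decimals of the display twins (JSON only).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         display_digits = 2L) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- if (is.data.frame(results)) results
          else as.data.frame(results, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.data.frame(results)) results <- as.list(results)
  out <- results
  for (nm in names(results)) {
    v <- results[[nm]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v)) {
      out[[paste0(nm, "_display")]] <- display_round(v, display_digits)
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
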