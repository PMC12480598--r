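#' Read a table of observations from CSV or TSV
#'
#' The delimiter is inferred from the file extension (`.tsv`/`.tab` for
#' tab-separated, comma otherwise). Required columns are checked up front;
#' rows with missing values in those columns are dropped with a message
#' giving the count. The missing-value token set is `""`, `"NA"`, `"NaN"`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param required Character vector of column names that must be present.
#' @param na Missing-value tokens.
#' @return A tibble.
#' @export
read_observations <- function(path, required = character(), na = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, na = na,
                           show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("parse error(s) in ", path, " at row(s) ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         ": ", probs$expected[1], " expected, got '", probs$actual[1], "'",
         call. = FALSE)
  }
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(required)) {
    ok <- stats::complete.cases(out[required])
    if (any(!ok)) {
      message(sum(!ok), " row(s) with missing values excluded")
      out <- out[ok, , drop = FALSE]
    }
  }
  out
}

#' Write an analysis report to CSV or JSON
#'
#' Numbers survive a round trip at full double precision: JSON is written
#' with unrounded digits, CSV through readr's full-precision formatting.
#' The format is inferred from the extension unless given.
#'
#' @param results A data frame, or a list of data frames / scalars for JSON.
#' @param path Output path ending in `.csv` or `.json`.
#' @param format `"csv"` or `"json"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    if (!is.data.frame(results)) {
      stop("CSV reports require a data frame; got ", class(results)[1],
           call. = FALSE)
    }
    readr::write_csv(results, path)
  }
  invisible(path)
}
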