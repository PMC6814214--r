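#' Read a contingency table from CSV/TSV/JSON
#'
#' CSV/TSV files hold a numeric block in the row-major (a, b / c, d)
#' layout for 2x2 input (larger blocks are returned as r x c matrices);
#' JSON holds an object \code{{"a":..,"b":..,"c":..,"d":..}}.  An optional
#' header row / label column is dropped with \code{labels = TRUE}.
#'
#' @param path File path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"json"}; default
#'   guesses from the extension.
#' @param labels Drop a header row and a leading label column (default
#'   FALSE).
#' @return A \code{count_table2x2} for 2x2 input, otherwise a numeric
#'   matrix.
#' @export
read_count_table <- function(path, format = NULL, labels = FALSE) {
  if (!file.exists(path)) stop_domain(sprintf("no such file: %s", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    need <- c("a", "b", "c", "d")
    if (!all(need %in% names(obj)))
      stop_domain("JSON table must have fields a, b, c, d")
    return(count_table(obj$a, obj$b, obj$c, obj$d))
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (labels && length(lines) > 1) lines <- lines[-1]
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (labels) parts <- lapply(parts, function(p) p[-1])
  widths <- lengths(parts)
  if (length(unique(widths)) != 1)
    stop_domain(sprintf("ragged table: line %d has %d fields, expected %d",
                        which(widths != widths[1])[1],
                        widths[widths != widths[1]][1], widths[1]))
  m <- do.call(rbind, lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(trimws(parts[[i]])))
    if (any(is.na(v)))
      stop_domain(sprintf("non-numeric entry on line %d", i))
    v
  }))
  if (all(dim(m) == c(2, 2))) as_count_table(m) else m
}

# Strip closures and other non-serializable members, recursively.
serializable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, serializable)
    x <- x[!vapply(x, is.null, logical(1))]
  }
  x
}

#' Write an analysis result to JSON or CSV
#'
#' JSON output is deterministic (stable key order, 12 significant digits)
#' and embeds metadata: package version, seed when available, and the
#' table orientation conventions.  CSV output is supported for tabular
#' results (data frames such as association scans and per-run Monte Carlo
#' summaries).
#'
#' @param result Any report object produced by the package.
#' @param path Output path.
#' @param format \code{"json"} or \code{"csv"}.
#' @param seed Seed to stamp into the metadata (optional).
#' @return Invisibly, the path written.
#' @export
write_report <- function(result, path, format = c("json", "csv"),
                         seed = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(result))
      stop_domain("CSV output requires a data frame result")
    utils::write.csv(result, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(
    metadata = list(
      package = "proptab",
      version = as.character(utils::packageVersion("proptab")),
      seed = seed,
      conventions = "2x2 cell order row-major (a,b/c,d); delta halved (center of mass); delta_c oriented c-minus-a"),
    result = serializable(unclass(result)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
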