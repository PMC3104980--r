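#' Load a single numeric series from a text file
#'
#' Reads one value per row from a plain-text or CSV file. An optional
#' single header row is skipped; values may be comma- or
#' whitespace-delimited (the first field of each row is used). Parse
#' failures name the offending line.
#'
#' @param path file path.
#' @return a numeric vector.
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop(sprintf("no data in %s", path), call. = FALSE)
  first_field <- function(s) strsplit(s, "[,[:space:]]+")[[1]][1]
  parse_from <- function(start) {
    out <- numeric(length(lines) - start + 1L)
    for (i in seq(start, length(lines))) {
      v <- suppressWarnings(as.numeric(first_field(lines[i])))
      if (is.na(v))
        stop(sprintf("cannot parse numeric value at line %d of %s: '%s'",
                     i, path, lines[i]), call. = FALSE)
      out[i - start + 1L] <- v
    }
    out
  }
  # header detection: if line 1 is non-numeric, skip it once
  if (is.na(suppressWarnings(as.numeric(first_field(lines[1]))))) {
    if (length(lines) == 1L)
      stop(sprintf("cannot parse numeric value at line 1 of %s: '%s'",
                   path, lines[1]), call. = FALSE)
    parse_from(2L)
  } else {
    parse_from(1L)
  }
}

#' Write a run report as JSON
#'
#' Serialises a report (config echo, results, seed, package version,
#' timestamp) to JSON with full double precision so that parsing it back
#' reproduces config and results exactly.
#'
#' @param report a named list; see [make_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a JSON run report
#'
#' @param path file written by [write_report()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Assemble a run report
#'
#' @param config a named list echoing the run configuration (including the
#'   root seed).
#' @param results a named list of results.
#' @param seed the root seed of the run.
#' @return a report list with `config`, `results`, `seed`, `version` and
#'   `timestamp` fields.
#' @export
make_report <- function(config, results, seed) {
  list(config = config,
       results = results,
       seed = seed,
       version = as.character(utils::packageVersion("cicover")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
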