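#' Read a binary response matrix from CSV
#'
#' Comma-separated 0/1 values, persons as rows. A single header row is
#' auto-detected (any token in the first row that is not 0 or 1). Violations
#' are reported with their row and column.
#'
#' @param path Path to the CSV file.
#' @return N x J integer matrix.
#' @export
readResponses <- function(path) {
  readBinaryCSV(path, what = "response matrix")
}

#' Read a Q-matrix from CSV
#'
#' Same dialect as [readResponses()] (items as rows, attributes as columns),
#' followed by the structural Q-matrix checks of [qMatrix()].
#'
#' @param path Path to the CSV file.
#' @return Validated J x K Q-matrix.
#' @export
readQmatrix <- function(path) {
  qMatrix(readBinaryCSV(path, what = "Q-matrix"))
}

readBinaryCSV <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(what, " file is empty: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- !all(trimws(cells[[1]]) %in% c("0", "1"))
  if (header) cells <- cells[-1]
  if (length(cells) == 0) stop(what, " has no data rows: ", path, call. = FALSE)
  ncols <- length(cells[[1]])
  out <- matrix(NA_integer_, length(cells), ncols)
  for (i in seq_along(cells)) {
    row <- trimws(cells[[i]])
    if (length(row) != ncols)
      stop(what, ": row ", i + header, " has ", length(row),
           " cells, expected ", ncols, call. = FALSE)
    bad <- which(!row %in% c("0", "1"))
    if (length(bad))
      stop(what, ": non-binary value '", row[bad[1]], "' at row ",
           i + header, ", column ", bad[1], call. = FALSE)
    out[i, ] <- as.integer(row)
  }
  out
}

#' Write a binary matrix as CSV
#'
#' Inverse of [readResponses()]/[readQmatrix()]: plain comma-separated 0/1
#' rows, optionally with a header.
#'
#' @param X Binary matrix.
#' @param path Output path.
#' @param header Write a header row of column names.
#' @export
writeBinaryCSV <- function(X, path, header = FALSE) {
  X <- as.matrix(X)
  utils::write.table(X, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Write an analysis report to JSON (and optionally CSV)
#'
#' Serializes a reliability report or condition summary: JSON at full
#' numeric precision for machines, and an optional flat CSV (4 decimals) for
#' tabular consumption.
#'
#' @param report A `cdmReliability` or `cdmCondition` object, or a plain
#'   named list of numbers.
#' @param path Output JSON path.
#' @param csv Optional CSV path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, csv = NULL) {
  payload <- reportPayload(report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv)) {
    flat <- unlist(payload)
    flat <- flat[vapply(flat, function(v) is.finite(suppressWarnings(as.numeric(v))),
                        TRUE)]
    utils::write.table(
      data.frame(quantity = names(flat),
                 value = sprintf("%.4f", as.numeric(flat))),
      csv, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

reportPayload <- function(report) {
  if (inherits(report, "cdmReliability"))
    list(method = report$method, tau = report$tau, tau_k = report$tauK)
  else if (inherits(report, "cdmCondition"))
    c(report$summary, list(failures = report$failures))
  else if (is.list(report)) report
  else stop("unsupported report type", call. = FALSE)
}
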