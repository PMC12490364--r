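#' Read two-group survival data from a delimited text file
#'
#' Columns are interpreted positionally as time, event, group (in that
#' order); a header row is auto-detected by default. Lines starting with
#' `#` are treated as comments (this package's writers embed their
#' generating parameters that way).
#'
#' @param path Path to the file.
#' @param header `NA` to auto-detect (default), or `TRUE`/`FALSE`.
#' @param delim Field delimiter, default comma.
#'
#' @return A [survival_data] object.
#' @export
read_survival_csv <- function(path, header = NA, delim = ",") {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.table(path, sep = delim, header = FALSE,
                      comment.char = "#", colClasses = "character",
                      strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop_invalid(sprintf("cannot parse %s: %s",
                                             path, conditionMessage(e)))
  )
  if (ncol(raw) < 3L) {
    stop_invalid(sprintf(
      "%s: expected at least 3 columns (time, event, group), found %d",
      path, ncol(raw)
    ))
  }
  if (is.na(header)) {
    first <- suppressWarnings(as.numeric(raw[1L, 1:3]))
    header <- anyNA(first)
  }
  if (header) {
    if (nrow(raw) < 2L) stop_invalid(sprintf("%s: no data rows", path))
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) < 2L) {
    stop_invalid(sprintf("%s: need at least 2 data rows", path))
  }
  cols <- c("time", "event", "group")
  vals <- vector("list", 3L)
  for (j in 1:3) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_invalid(sprintf(
        "%s: non-numeric %s value '%s' at row %d",
        path, cols[j], raw[bad[1L], j], bad[1L]
      ))
    }
    vals[[j]] <- v
  }
  bad_t <- which(!is.finite(vals[[1L]]) | vals[[1L]] <= 0)
  if (length(bad_t)) {
    stop_invalid(sprintf(
      "%s: time must be positive and finite; offending value %s at row %d",
      path, raw[bad_t[1L], 1L], bad_t[1L]
    ))
  }
  for (j in 2:3) {
    bad <- which(!vals[[j]] %in% c(0, 1))
    if (length(bad)) {
      stop_invalid(sprintf(
        "%s: %s must be 0 or 1; offending value '%s' at row %d (column %d)",
        path, cols[j], raw[bad[1L], j], bad[1L], j
      ))
    }
  }
  survival_data(vals[[1L]], vals[[2L]], vals[[3L]])
}

#' Write two-group survival data as CSV
#'
#' Writes the three-column (time, event, group) convention with full
#' double precision. An optional metadata string is embedded as a
#' leading `#` comment line so the file records how it was generated.
#'
#' @param data A [survival_data] object.
#' @param path Output path.
#' @param meta Optional single-line metadata string (e.g. seed and
#'   generating parameters).
#' @export
write_survival_csv <- function(data, path, meta = NULL) {
  if (!inherits(data, "survival_data")) {
    stop_invalid("data must be a survival_data object")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  writeLines("time,event,group", con)
  writeLines(sprintf("%.17g,%d,%d", data$time, as.integer(data$event),
                     as.integer(data$group)), con)
  invisible(path)
}
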