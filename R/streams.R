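#' Multichannel stream
#'
#' Uniform-rate, timestamped multichannel time series: the carrier for raw EEG
#' (e.g. 32 channels at 500 Hz) and for the 30 Hz valence stream. Timestamps
#' are implicit: sample i (1-based) lies at `start_time + (i - 1) / rate`
#' seconds.
#'
#' @param samples numeric matrix, one row per sample, one column per channel.
#' @param rate sampling rate in Hz (> 0).
#' @param labels character vector of channel names, one per column.
#' @param start_time time of the first sample in seconds.
#' @return An object of class `multichannel_stream` with fields `samples`,
#'   `rate`, `labels`, `start_time`.
#' @export
multichannel_stream <- function(samples, rate, labels = colnames(samples),
                                start_time = 0) {
  samples <- as.matrix(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(samples)))
  labels <- as.character(labels)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (ncol(samples) != length(labels))
    stop("number of columns (", ncol(samples), ") does not match number of labels (",
         length(labels), ")")
  if (anyNA(samples))
    stop("stream samples contain NA/NaN (first at row ",
         which(rowSums(is.na(samples)) > 0)[1L], ")")
  storage.mode(samples) <- "double"
  colnames(samples) <- labels
  structure(
    list(samples = samples, rate = as.numeric(rate), labels = labels,
         start_time = as.numeric(start_time)),
    class = "multichannel_stream"
  )
}

#' @export
print.multichannel_stream <- function(x, ...) {
  cat(sprintf("<multichannel_stream> %d channel(s) x %d samples @ %g Hz (%.2f s from t=%g)\n",
              ncol(x$samples), nrow(x$samples), x$rate,
              nrow(x$samples) / x$rate, x$start_time))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / duration of a stream
#' @param stream a [multichannel_stream()].
#' @return `stream_length`: integer sample count. `stream_duration`: seconds.
#' @export
stream_length <- function(stream) nrow(stream$samples)

#' @rdname stream_length
#' @export
stream_duration <- function(stream) nrow(stream$samples) / stream$rate

#' Sample timestamps of a stream (seconds)
#' @param stream a [multichannel_stream()].
#' @export
stream_times <- function(stream) {
  stream$start_time + (seq_len(nrow(stream$samples)) - 1L) / stream$rate
}

infer_fmt <- function(path, fmt) {
  if (!is.null(fmt)) return(match.arg(fmt, c("csv", "jsonl")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson")) "jsonl" else "csv"
}

#' Read a timed multichannel stream from disk
#'
#' Two self-describing plain-text formats are supported. CSV: a first comment
#' line `# rate=<Hz> start=<s>`, then a header row of channel labels, then one
#' row per sample. JSONL: a header object `{"labels": [...], "rate": ...,
#' "start_time": ...}` followed by one object per sample keyed by label.
#'
#' @param path file to read.
#' @param fmt `"csv"` or `"jsonl"`; inferred from the extension when `NULL`.
#' @return A [multichannel_stream()].
#' @seealso [write_stream()]
#' @export
read_stream <- function(path, fmt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- infer_fmt(path, fmt)
  if (fmt == "csv") read_stream_csv(path) else read_stream_jsonl(path)
}

read_stream_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[[1L]], "#"))
    stop("malformed stream CSV: expected '# rate=<Hz> start=<s>' header in ", path)
  meta <- parse_meta_line(lines[[1L]])
  labels <- strsplit(lines[[2L]], ",", fixed = TRUE)[[1L]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  n <- length(body)
  samples <- matrix(NA_real_, nrow = n, ncol = length(labels))
  for (i in seq_len(n)) {
    vals <- strsplit(body[[i]], ",", fixed = TRUE)[[1L]]
    if (length(vals) != length(labels))
      stop("row ", i, " has ", length(vals), " values for ", length(labels),
           " labels in ", path)
    v <- suppressWarnings(as.numeric(vals))
    if (anyNA(v))
      stop("row ", i, " contains a missing or non-numeric value in ", path)
    samples[i, ] <- v
  }
  multichannel_stream(samples, rate = meta$rate, labels = labels,
                      start_time = meta$start)
}

parse_meta_line <- function(line) {
  line <- sub("^#\\s*", "", line)
  kv <- strsplit(strsplit(line, "\\s+")[[1L]], "=", fixed = TRUE)
  out <- list(rate = NA_real_, start = 0)
  for (p in kv) {
    if (length(p) == 2L && p[[1L]] %in% c("rate", "start"))
      out[[p[[1L]]]] <- as.numeric(p[[2L]])
  }
  if (!is.finite(out$rate)) stop("stream CSV header does not declare a rate")
  out
}

read_stream_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty JSONL stream: ", path)
  header <- jsonlite::fromJSON(lines[[1L]])
  if (is.null(header$labels) || is.null(header$rate))
    stop("JSONL stream header must declare labels and rate: ", path)
  labels <- as.character(header$labels)
  body <- lines[-1L]
  samples <- matrix(NA_real_, nrow = length(body), ncol = length(labels))
  for (i in seq_along(body)) {
    rec <- jsonlite::fromJSON(body[[i]])
    if (!all(labels %in% names(rec)))
      stop("row ", i, " is missing channel(s): ",
           paste(setdiff(labels, names(rec)), collapse = ", "))
    v <- as.numeric(unlist(rec[labels]))
    if (length(v) != length(labels) || anyNA(v))
      stop("row ", i, " contains a missing or non-numeric value in ", path)
    samples[i, ] <- v
  }
  st <- if (is.null(header$start_time)) 0 else as.numeric(header$start_time)
  multichannel_stream(samples, rate = as.numeric(header$rate), labels = labels,
                      start_time = st)
}

#' Write a timed multichannel stream to disk
#'
#' @inheritParams read_stream
#' @param stream a [multichannel_stream()].
#' @param digits significant digits written (default 15, float round-trip safe).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, fmt = NULL, digits = 15) {
  stopifnot(inherits(stream, "multichannel_stream"))
  fmt <- infer_fmt(path, fmt)
  if (fmt == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# rate=%.10g start=%.10g", stream$rate, stream$start_time), con)
    writeLines(paste(stream$labels, collapse = ","), con)
    body <- apply(stream$samples, 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = ","))
    if (length(body)) writeLines(body, con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(
      list(labels = stream$labels, rate = stream$rate,
           start_time = stream$start_time),
      auto_unbox = TRUE, digits = NA), con)
    for (i in seq_len(nrow(stream$samples))) {
      rec <- as.list(stream$samples[i, ])
      names(rec) <- stream$labels
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Session event log
#'
#' Ordered record of everything a session does: per-epoch controller
#' evaluations, speed adaptations, valence judgments, threshold trajectories
#' and game events (line clears, deaths). Each record is a named list with at
#' least `t` (seconds) and `type`.
#'
#' @param records list of records.
#' @return An object of class `event_log`.
#' @export
event_log <- function(records = list()) {
  t <- vapply(records, function(r) as.numeric(r$t), numeric(1))
  if (length(t) > 1L && any(diff(t) < 0))
    stop("event log timestamps must be non-decreasing")
  structure(list(records = records), class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  types <- vapply(x$records, function(r) r$type, character(1))
  cat(sprintf("<event_log> %d record(s)\n", length(x$records)))
  if (length(types)) print(table(types))
  invisible(x)
}

#' @export
length.event_log <- function(x) length(x$records)

#' Filter an event log by record type
#' @param log an [event_log()].
#' @param type record type, e.g. `"epoch"`, `"adaptation"`, `"death"`.
#' @return list of records of that type, in order.
#' @export
log_records <- function(log, type = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(type)) return(log$records)
  Filter(function(r) identical(r$type, type), log$records)
}

#' Write / read an event log as JSON Lines
#'
#' One JSON object per record; order and all numeric fields are preserved.
#'
#' @param log an [event_log()].
#' @param path file path.
#' @return `write_event_log`: `path` invisibly; `read_event_log`: an
#'   [event_log()].
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in log$records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE))
  event_log(recs)
}
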