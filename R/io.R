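# Plain-text artifact I/O: event annotations, time-in-bed spans, SpO2 traces.

#' Write / read event annotations as CSV
#'
#' Header `start_s,end_s,type`.
#'
#' @param events An [event_set()].
#' @param path File path.
#' @return `read_events_csv` returns an [event_set()].
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(start_s = events$start, end_s = events$end,
                              type = events$type),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_set(d$start_s, d$end_s, type = d$type)
}

#' Write / read time-in-bed spans as CSV
#'
#' Header `start_s,end_s`.
#'
#' @param spans data.frame with `start`, `end` (s).
#' @param path File path.
#' @return `read_spans_csv` returns the spans data.frame.
#' @export
write_spans_csv <- function(spans, path) {
  utils::write.csv(data.frame(start_s = spans$start, end_s = spans$end),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spans_csv
#' @export
read_spans_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(start = d$start_s, end = d$end_s)
}

#' Write an SpO2 trace as CSV
#'
#' Header `time_s,spo2_pct`.
#'
#' @param spo2 SpO2 trace, percent.
#' @param fs Sampling rate, Hz.
#' @param path File path.
#' @export
write_spo2_csv <- function(spo2, fs, path) {
  utils::write.csv(data.frame(time_s = (seq_along(spo2) - 1) / fs,
                              spo2_pct = spo2),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
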