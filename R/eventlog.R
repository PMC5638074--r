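#' Physiological event log
#'
#' The retrospective-gating record: R-wave times, respiration windows and the
#' timestamp of every acquired RF line. Reconstruction consumes only this
#' object plus the k-line stream, so a log read from disk is interchangeable
#' with one produced by the simulator.
#'
#' @param rwave_times numeric vector of R-wave event times, ms, strictly
#'   increasing.
#' @param resp_intervals two-column matrix (start, end) of respiration
#'   windows, ms, with start < end.
#' @param rf data frame with columns `time`, `rep_index`, `pe_index`, one row
#'   per acquired line, times strictly increasing.
#' @return an object of class `event_log`.
#' @export
event_log <- function(rwave_times = numeric(0),
                      resp_intervals = matrix(numeric(0), ncol = 2),
                      rf = data.frame(time = numeric(0),
                                      rep_index = integer(0),
                                      pe_index = integer(0))) {
  if (is.unsorted(rwave_times, strictly = TRUE))
    htr_stop("format_error", "rwave_times must be strictly increasing")
  resp_intervals <- matrix(as.numeric(resp_intervals), ncol = 2,
                           dimnames = list(NULL, c("start", "end")))
  if (nrow(resp_intervals) && any(resp_intervals[, 1] >= resp_intervals[, 2]))
    htr_stop("format_error", "every respiration interval needs start < end")
  if (!all(c("time", "rep_index", "pe_index") %in% names(rf)))
    htr_stop("format_error", "rf must have columns time, rep_index, pe_index")
  if (nrow(rf) > 1L && is.unsorted(rf$time, strictly = TRUE))
    htr_stop("format_error", "RF times must be strictly increasing")
  structure(list(rwave_times = as.numeric(rwave_times),
                 resp_intervals = resp_intervals,
                 rf = rf),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("event_log: %d R-waves, %d respiration windows, %d RF lines\n",
              length(x$rwave_times), nrow(x$resp_intervals), nrow(x$rf)))
  invisible(x)
}

#' Write / read an event log as CSV
#'
#' The interchange dialect is a four-column CSV,
#' `time_ms,event_type,rep_index,pe_index`, with `event_type` one of `R`,
#' `RESP_START`, `RESP_END`, `RF` (the last two columns are empty except on
#' `RF` rows). Rows are sorted by time; timestamps carry six decimal places
#' (1 ns granularity), so a write/read round trip preserves times to well
#' under 1 us. Readers validate rather than repair: unknown event types,
#' non-monotonic RF times and unbalanced respiration markers raise a format
#' error naming the offending line.
#'
#' @param log an [event_log()].
#' @param path file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an `event_log` (an empty file yields an empty log with a
#'   warning).
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  rows <- rbind(
    data.frame(time_ms = log$rwave_times, event_type = "R",
               rep_index = NA_integer_, pe_index = NA_integer_),
    data.frame(time_ms = as.numeric(log$resp_intervals[, 1]),
               event_type = rep("RESP_START", nrow(log$resp_intervals)),
               rep_index = NA_integer_, pe_index = NA_integer_),
    data.frame(time_ms = as.numeric(log$resp_intervals[, 2]),
               event_type = rep("RESP_END", nrow(log$resp_intervals)),
               rep_index = NA_integer_, pe_index = NA_integer_),
    data.frame(time_ms = log$rf$time, event_type = rep("RF", nrow(log$rf)),
               rep_index = log$rf$rep_index, pe_index = log$rf$pe_index))
  rows <- rows[order(rows$time_ms, match(rows$event_type,
                                         c("RESP_END", "R", "RESP_START", "RF"))), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,event_type,rep_index,pe_index", con)
  writeLines(sprintf("%.6f,%s,%s,%s", rows$time_ms, rows$event_type,
                     ifelse(is.na(rows$rep_index), "", rows$rep_index),
                     ifelse(is.na(rows$pe_index), "", rows$pe_index)),
             con)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path))
    htr_stop("format_error", "no such file: %s", path)
  df <- utils::read.csv(path, colClasses = c("numeric", "character",
                                             "integer", "integer"))
  if (nrow(df) == 0L) {
    warning("empty event log: ", path)
    return(event_log())
  }
  known <- c("R", "RESP_START", "RESP_END", "RF")
  bad <- which(!df$event_type %in% known)
  if (length(bad))
    htr_stop("format_error", "unknown event_type '%s' at line %d",
             df$event_type[bad[1]], bad[1] + 1L)  # +1 for the header line

  rf <- df[df$event_type == "RF", ]
  if (nrow(rf) > 1L) {
    nm <- which(diff(rf$time_ms) <= 0)
    if (length(nm))
      htr_stop("format_error", "non-monotonic RF time at line %d",
               as.integer(rownames(rf)[nm[1] + 1L]) + 1L)
  }

  # pair respiration markers in time order
  resp_rows <- df[df$event_type %in% c("RESP_START", "RESP_END"), ]
  starts <- numeric(0); open <- NA_real_
  iv <- matrix(numeric(0), ncol = 2)
  if (nrow(resp_rows)) {
    for (i in seq_len(nrow(resp_rows))) {
      ty <- resp_rows$event_type[i]
      tm <- resp_rows$time_ms[i]
      line_no <- as.integer(rownames(resp_rows)[i]) + 1L
      if (ty == "RESP_START") {
        if (!is.na(open))
          htr_stop("format_error", "RESP_START before previous RESP_END at line %d", line_no)
        open <- tm
      } else {
        if (is.na(open) || tm <= open)
          htr_stop("format_error", "RESP_END without matching RESP_START at line %d", line_no)
        iv <- rbind(iv, c(open, tm))
        open <- NA_real_
      }
    }
    if (!is.na(open))
      htr_stop("format_error", "unterminated respiration window starting at %.3f ms", open)
  }

  event_log(rwave_times = df$time_ms[df$event_type == "R"],
            resp_intervals = iv,
            rf = data.frame(time = rf$time_ms, rep_index = rf$rep_index,
                            pe_index = rf$pe_index))
}

#' Read a trial table
#'
#' Parses per-subject, per-trial parameter estimates (e.g. E/A or EF over
#' repeated scans) from a CSV with header `subject_id,trial,label,value`.
#' Rows with value `NA` are excluded with a warning; duplicate
#' (subject, trial, label) keys are a format error.
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `trial_table` with columns `subject_id`
#'   (character), `trial` (integer), `label` (character), `value` (numeric).
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path))
    htr_stop("format_error", "no such file: %s", path)
  df <- utils::read.csv(path, colClasses = c("character", "integer",
                                             "character", "numeric"))
  need <- c("subject_id", "trial", "label", "value")
  if (!identical(names(df), need))
    htr_stop("format_error", "trial table header must be %s",
             paste(need, collapse = ","))
  drop <- !is.finite(df$value)
  if (any(drop)) {
    warning(sum(drop), " row(s) with missing value excluded")
    df <- df[!drop, , drop = FALSE]
  }
  key <- paste(df$subject_id, df$trial, df$label, sep = "\r")
  if (anyDuplicated(key))
    htr_stop("format_error", "duplicate (subject_id, trial, label): %s",
             gsub("\r", "/", key[duplicated(key)][1]))
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write a trial table
#'
#' Deterministic CSV writer matching [read_trial_table()]'s dialect.
#'
#' @param table a data frame with columns `subject_id,trial,label,value`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  need <- c("subject_id", "trial", "label", "value")
  if (!all(need %in% names(table)))
    htr_stop("format_error", "trial table needs columns %s",
             paste(need, collapse = ","))
  utils::write.csv(as.data.frame(table)[, need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
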