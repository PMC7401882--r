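#' Timestamped activity log
#'
#' Ground-truth record of which protocol activity was performed when, used
#' as the reference for second-by-second evaluation. Entries are
#' non-overlapping, sorted, and use seconds relative to the start of the
#' recording (wall-clock logs are converted via the recording's
#' `start_time` anchor before construction).
#'
#' @param label character vector of activity names.
#' @param start,end numeric interval bounds in seconds, `start < end`.
#' @return An object of class `activity_log`: a `data.frame` with columns
#'   `label`, `start`, `end`.
#' @examples
#' activity_log(c("sit", "stand"), start = c(0, 95), end = c(90, 185))
#' @export
activity_log <- function(label, start, end) {
  if (!(length(label) == length(start) && length(start) == length(end))) {
    stop("label, start and end must have equal length")
  }
  df <- data.frame(label = as.character(label), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop("activity log entries with start >= end at rows: ",
         paste(bad, collapse = ", "))
  }
  if (is.unsorted(df$start, strictly = TRUE)) {
    stop("activity log entries must be sorted by start time")
  }
  if (nrow(df) > 1L) {
    overlap <- which(df$start[-1L] < df$end[-nrow(df)])
    if (length(overlap)) {
      stop("overlapping activity log entries at rows: ",
           paste(overlap + 1L, collapse = ", "))
    }
  }
  class(df) <- c("activity_log", "data.frame")
  df
}

#' Read an activity log from CSV
#'
#' Expects columns `label`, `start_s`, `end_s` (header optional; comma or
#' semicolon delimited). A start-only log — `end_s` absent or `NA` except
#' in the final row — is accepted: each end is inferred from the next
#' entry's start, but the last entry must state its end explicitly.
#'
#' @param path path to the log file.
#' @return An [activity_log()].
#' @export
read_activity_log <- function(path) {
  if (!file.exists(path)) stop("activity log file not found: ", path)
  dt <- data.table::fread(path, header = "auto", sep = "auto",
                          showProgress = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop("activity log '", path, "' must contain label and start columns")
  }
  label <- as.character(dt[[1L]])
  start <- as.numeric(dt[[2L]])
  end <- if (ncol(dt) >= 3L) as.numeric(dt[[3L]]) else rep(NA_real_, nrow(dt))
  if (anyNA(start)) {
    stop("non-numeric start time in '", path, "' at row ",
         which(is.na(start))[1L])
  }
  miss <- is.na(end)
  if (any(miss)) {
    if (miss[length(miss)]) {
      stop("last activity log entry requires an explicit end time")
    }
    infer <- which(miss)
    end[infer] <- start[infer + 1L]
  }
  activity_log(label, start, end)
}

#' Write an activity log to CSV
#' @param log an [activity_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_log <- function(log, path) {
  stopifnot(inherits(log, "activity_log"))
  data.table::fwrite(data.table::data.table(label = log$label,
                                            start_s = log$start,
                                            end_s = log$end),
                     path, quote = FALSE)
  invisible(path)
}

#' Trim a lead-in period from every log entry
#'
#' Advances each entry's start by `lead_in` seconds, dropping entries whose
#' remaining duration is zero or negative. Used to discard the settling
#' period at the start of each protocol activity (the school protocol
#' discards the first 60 s of each 5-min activity).
#'
#' @param log an [activity_log()].
#' @param lead_in seconds to discard at the start of each entry (>= 0).
#' @return A trimmed [activity_log()].
#' @examples
#' log <- activity_log("walk", 0, 300)
#' trim_log(log, 60)
#' @export
trim_log <- function(log, lead_in) {
  stopifnot(inherits(log, "activity_log"))
  if (!is.numeric(lead_in) || length(lead_in) != 1L || lead_in < 0) {
    stop("`lead_in` must be a single non-negative number of seconds")
  }
  start <- log$start + lead_in
  keep <- start < log$end
  if (!any(keep)) {
    return(structure(data.frame(label = character(), start = numeric(),
                                end = numeric(), stringsAsFactors = FALSE),
                     class = c("activity_log", "data.frame")))
  }
  activity_log(log$label[keep], start[keep], log$end[keep])
}
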