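#' Triaxial acceleration recording
#'
#' Container for a time-ordered triaxial acceleration signal in units of g
#' at a constant sampling frequency. A recording is either in the
#' `"raw_device"` frame (axes as the device reports them) or in the
#' `"canonical"` anatomical frame, where axis 1 is longitudinal along the
#' thigh (positive toward the knee, so quiet upright standing reads about
#' +1 g), axis 2 is anterior (forward positive) and axis 3 is lateral.
#'
#' @param samples numeric matrix with one row per sample and three columns
#'   (acceleration in g). A plain vector of length 3 is treated as one sample.
#' @param fs sampling frequency in Hz (single positive number).
#' @param frame `"raw_device"` or `"canonical"`.
#' @param start_time optional wall-clock anchor for sample 1, either a
#'   `POSIXct` or a number of epoch seconds. Used to convert wall-clock
#'   activity logs to recording-relative seconds.
#' @return An object of class `triaxial_recording`: a list with elements
#'   `samples` (n x 3 matrix), `fs`, `frame` and `start_time`.
#' @examples
#' rec <- triaxial_recording(matrix(c(1, 0, 0), 1, 3), fs = 30,
#'                           frame = "canonical")
#' n_samples(rec)
#' @export
triaxial_recording <- function(samples, fs, frame = c("raw_device", "canonical"),
                               start_time = NULL) {
  frame <- match.arg(frame)
  if (is.vector(samples) && is.numeric(samples) && length(samples) == 3L) {
    samples <- matrix(samples, nrow = 1L)
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) != 3L) {
    stop("`samples` must have exactly 3 columns (got ", ncol(samples), ")")
  }
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (!is.null(start_time)) {
    start_time <- as.numeric(start_time)
    if (length(start_time) != 1L || !is.finite(start_time)) {
      stop("`start_time` must be a single time point")
    }
  }
  colnames(samples) <- if (frame == "canonical") c("long", "ant", "lat")
                       else c("ax1", "ax2", "ax3")
  structure(list(samples = samples, fs = as.numeric(fs), frame = frame,
                 start_time = start_time),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %d samples @ %g Hz (%.1f s), frame: %s\n",
              n_samples(x), x$fs, duration(x), x$frame))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a [triaxial_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Duration of a recording in seconds
#' @param rec a [triaxial_recording()].
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read a raw recording from CSV
#'
#' Reads a triaxial recording written as delimited text with three numeric
#' acceleration columns in g and an optional leading timestamp column
#' (ISO-8601 or epoch seconds). Comma and semicolon delimiters and an
#' optional header row are auto-detected. The result is in the
#' `"raw_device"` frame; pass it through [remap_to_canonical()] before
#' feature extraction.
#'
#' When a timestamp column is present the sampling frequency is also
#' inferred from the stamps; a relative mismatch above 1% with the declared
#' `fs` raises a warning naming both rates.
#'
#' @param path path to the CSV file.
#' @param fs declared sampling frequency in Hz.
#' @return A [triaxial_recording()] in the raw device frame, with
#'   `start_time` set when a timestamp column is present.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = "auto", sep = "auto",
                      colClasses = NULL, showProgress = FALSE),
    error = function(e) stop("cannot parse recording file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L || ncol(dt) < 3L) {
    stop("recording file '", path,
         "' must contain at least 3 acceleration columns and one row")
  }
  start_time <- NULL
  if (ncol(dt) >= 4L) {
    ts_col <- dt[[1L]]
    ts <- parse_timestamps(ts_col)
    dt <- dt[, -1L, with = FALSE]
    if (!is.null(ts)) {
      start_time <- ts[1L]
      if (length(ts) > 1L) {
        fs_inferred <- (length(ts) - 1) / (ts[length(ts)] - ts[1L])
        if (is.finite(fs_inferred) &&
            abs(fs_inferred - fs) / fs > 0.01) {
          warning(sprintf(
            "declared fs = %g Hz but timestamps imply %.4g Hz", fs,
            fs_inferred))
        }
      }
    }
  }
  if (ncol(dt) > 3L) dt <- dt[, 1:3, with = FALSE]
  bad <- which(!vapply(dt, is.numeric, logical(1)))
  if (length(bad)) {
    # locate the first offending row for the error message
    col <- dt[[bad[1L]]]
    row <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
    stop("non-numeric acceleration value in '", path, "' at data row ",
         ifelse(is.na(row), 1L, row), ", column ", bad[1L])
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    stop("missing acceleration value in '", path, "' at data row ",
         which(!stats::complete.cases(m))[1L])
  }
  triaxial_recording(m, fs = fs, frame = "raw_device",
                     start_time = start_time)
}

# Accepts ISO-8601 strings or numeric epoch/relative seconds; NULL when the
# column cannot be interpreted as time.
parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  x <- as.character(x)
  t <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                   tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%d %H:%M:%OS")))
  if (anyNA(t)) NULL else as.numeric(t)
}

#' Write a recording to CSV
#'
#' Writes the three acceleration columns (and, when present, a leading
#' epoch-second timestamp column) with enough significant digits that
#' [read_recording()] recovers every sample bit-exactly.
#'
#' @param rec a [triaxial_recording()].
#' @param path output path.
#' @param timestamps write a leading timestamp column (requires
#'   `rec$start_time`); default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, timestamps = FALSE) {
  stopifnot(inherits(rec, "triaxial_recording"))
  df <- data.table::as.data.table(rec$samples)
  data.table::setnames(df, c("ax", "ay", "az"))
  if (timestamps) {
    if (is.null(rec$start_time)) {
      stop("recording has no start_time anchor; cannot write timestamps")
    }
    ts <- rec$start_time + (seq_len(n_samples(rec)) - 1L) / rec$fs
    df <- cbind(data.table::data.table(timestamp = ts), df)
  }
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  out <- df[, lapply(.SD, fmt)]
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Resample a recording to a lower rate
#'
#' Rational-ratio resampling of each axis to `target_fs`. The default
#' `"polyphase"` method upsamples by the rational factor L, applies a
#' Hamming-windowed-sinc anti-aliasing low-pass at the narrower of the two
#' Nyquist limits, and decimates by M, preserving total duration to within
#' one output sample period. The `"naive"` method picks the nearest raw
#' sample at each output instant with no filtering; it exists only for
#' strict replication of pipelines that decimated without anti-aliasing.
#'
#' @param rec a [triaxial_recording()].
#' @param target_fs target sampling frequency in Hz; must not exceed
#'   `rec$fs`.
#' @param method `"polyphase"` (default) or `"naive"`.
#' @return A [triaxial_recording()] at `target_fs` in the same frame.
#' @examples
#' rec <- triaxial_recording(matrix(rnorm(3000), ncol = 3), fs = 100)
#' resample_recording(rec, 30)
#' @export
resample_recording <- function(rec, target_fs, method = c("polyphase", "naive")) {
  stopifnot(inherits(rec, "triaxial_recording"))
  method <- match.arg(method)
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("`target_fs` must be a single positive number")
  }
  if (target_fs > rec$fs) {
    stop("upsampling not supported: target_fs (", target_fs,
         ") exceeds recording fs (", rec$fs, ")")
  }
  if (target_fs == rec$fs) return(rec)
  out <- switch(method,
    polyphase = apply(rec$samples, 2L,
                      resample_rational, fs = rec$fs, target = target_fs),
    naive = {
      n_out <- floor(n_samples(rec) * target_fs / rec$fs)
      idx <- pmin(n_samples(rec),
                  round((seq_len(n_out) - 1L) * rec$fs / target_fs) + 1L)
      rec$samples[idx, , drop = FALSE]
    })
  triaxial_recording(out, fs = target_fs, frame = rec$frame,
                     start_time = rec$start_time)
}

# Polyphase rational resampler for one channel: upsample by L (zero
# stuffing), windowed-sinc low-pass with gain L and cutoff at the narrower
# Nyquist, decimate by M. Filter delay is compensated so output sample k
# estimates the signal at time (k-1)/target_fs. Edges are reflect-padded.
resample_rational <- function(x, fs, target) {
  r <- rational_ratio(target / fs)
  L <- r[1L]; M <- r[2L]
  n_out <- floor(length(x) * L / M)
  # windowed-sinc prototype at the upsampled rate fs*L
  cutoff <- 1 / (2 * max(L, M))        # cycles per upsampled sample
  taps_half <- min(10L * max(L, M), length(x) * L - 2L)
  k <- seq(-taps_half, taps_half)
  h <- 2 * cutoff * sinc(2 * cutoff * k) *
    (0.54 + 0.46 * cos(pi * k / taps_half))   # Hamming window
  h <- h * L / sum(h)                          # unity passband gain after L
  # zero-stuff, reflect-pad by the filter half-length, convolve, decimate
  up <- numeric(length(x) * L)
  up[seq(1L, length(up), by = L)] <- x
  pad <- taps_half
  up_p <- c(rev(up[2:(pad + 1L)]), up, rev(up[(length(up) - pad):(length(up) - 1L)]))
  y <- stats::filter(up_p, h, method = "convolution", sides = 2L)
  y <- y[(pad + 1L):(pad + length(up))]
  y[seq(1L, by = M, length.out = n_out)]
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Smallest integer pair (L, M) with L/M equal to `ratio` (within 1e-9),
# searched over denominators up to 1000.
rational_ratio <- function(ratio) {
  for (M in 1:1000) {
    L <- ratio * M
    if (abs(L - round(L)) < 1e-9) return(c(as.integer(round(L)), M))
  }
  stop("cannot express resampling ratio ", ratio, " as a small rational")
}
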