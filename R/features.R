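#' Plan the analysis windows over a recording
#'
#' Windows are `win_s` seconds wide and advance by
#' `win_s * (1 - overlap)` seconds, aligned to the first sample. With the
#' defaults (2-s windows, 50% overlap) one window starts every second, so
#' the feature stream has exactly 1-s spacing. Any trailing partial window
#' is discarded; the window count is
#' `floor((n_samples - W) / H) + 1` with `W = win_s * fs` and
#' `H = W * (1 - overlap)`.
#'
#' @param n_samples number of samples in the recording.
#' @param fs sampling frequency in Hz.
#' @param win_s window width in seconds (default 2).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return A data.frame with one row per window: integer columns `start`
#'   and `end` (inclusive 1-based sample indices).
#' @examples
#' window_plan(300, fs = 30)   # 9 windows of 60 samples, hop 30
#' @export
window_plan <- function(n_samples, fs, win_s = 2, overlap = 0.5) {
  w <- win_s * fs
  h <- w * (1 - overlap)
  if (abs(w - round(w)) > 1e-9 || abs(h - round(h)) > 1e-9) {
    stop("window (", w, ") and hop (", h, ") must be whole sample counts")
  }
  w <- as.integer(round(w)); h <- as.integer(round(h))
  if (h < 1L) stop("overlap too large: hop must be at least one sample")
  if (n_samples < w) {
    stop("recording too short: ", n_samples, " samples < one ", win_s,
         "-s window (", w, " samples)")
  }
  k <- (n_samples - w) %/% h + 1L
  start <- (seq_len(k) - 1L) * h + 1L
  data.frame(start = start, end = start + w - 1L)
}

#' Compute per-window signal features
#'
#' For each 2-s, 50%-overlap window of a canonical-frame recording at the
#' 30 Hz working rate, computes the four features used by the decision
#' tree:
#' \describe{
#'   \item{`sd_long`}{standard deviation (population, N denominator) of
#'     the longitudinal acceleration, in g — the movement-intensity
#'     feature;}
#'   \item{`sd_max`}{maximum of the three per-axis standard deviations, in
#'     g — separates standing still from shuffling;}
#'   \item{`inc_deg`}{thigh inclination: the angle between the window-mean
#'     acceleration vector and the longitudinal axis, in degrees
#'     (`acos(m_long / |m|)`); about 0 upright, about 90 with a horizontal
#'     thigh;}
#'   \item{`theta_deg`}{forward/backward angle: `asin(m_ant / |m|)` in
#'     degrees, forward positive; persistently elevated during seated
#'     pedalling, near zero on average during gait.}
#' }
#' Windows whose mean-vector norm falls below 0.1 g give unreliable
#' angles; both angles are set to 0 and the frame is flagged
#' (`flag_undefined`).
#'
#' @param rec a [triaxial_recording()] in the `"canonical"` frame.
#' @param fs_expected working rate the recording must be at (default
#'   30 Hz); set to `NA` to accept any rate.
#' @param win_s,overlap window geometry passed to [window_plan()].
#' @return An object of class `feature_frames`: a data.frame with one row
#'   per window and columns `t` (window-centre time, s), `sd_long`,
#'   `sd_ap`, `sd_lat`, `sd_max`, `inc_deg`, `theta_deg`, `mean_long`,
#'   `mean_ap`, `mean_lat`, `flag_undefined`.
#' @export
compute_features <- function(rec, fs_expected = 30, win_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (rec$frame != "canonical") {
    stop("recording must be in the canonical frame; apply ",
         "remap_to_canonical() with the device orientation first")
  }
  if (!is.na(fs_expected) && rec$fs != fs_expected) {
    stop("recording is at ", rec$fs, " Hz but the working rate is ",
         fs_expected, " Hz; resample_recording() it first")
  }
  plan <- window_plan(n_samples(rec), rec$fs, win_s = win_s,
                      overlap = overlap)
  x <- rec$samples
  n <- nrow(plan)
  w <- plan$end[1L] - plan$start[1L] + 1L
  # gather windows into a (w x n) index matrix per axis; population SD
  idx <- outer(seq_len(w) - 1L, plan$start, `+`)
  stat_axis <- function(col) {
    m <- matrix(x[idx, col], nrow = w)
    mu <- colMeans(m)
    # two-pass centred SD: avoids cancellation on near-constant windows
    list(mean = mu, sd = sqrt(colMeans(sweep(m, 2L, mu)^2)))
  }
  a1 <- stat_axis(1L); a2 <- stat_axis(2L); a3 <- stat_axis(3L)
  sd_long <- a1$sd; sd_ap <- a2$sd; sd_lat <- a3$sd
  norm <- sqrt(a1$mean^2 + a2$mean^2 + a3$mean^2)
  undef <- norm < 0.1
  safe_norm <- ifelse(undef, NA_real_, norm)
  inc <- acos(pmin(pmax(a1$mean / safe_norm, -1), 1)) * 180 / pi
  theta <- asin(pmin(pmax(a2$mean / safe_norm, -1), 1)) * 180 / pi
  inc[undef] <- 0
  theta[undef] <- 0
  out <- data.frame(
    t = (plan$start - 1 + w / 2) / rec$fs,
    sd_long = sd_long, sd_ap = sd_ap, sd_lat = sd_lat,
    sd_max = pmax(sd_long, sd_ap, sd_lat),
    inc_deg = inc, theta_deg = theta,
    mean_long = a1$mean, mean_ap = a2$mean, mean_lat = a3$mean,
    flag_undefined = undef)
  class(out) <- c("feature_frames", "data.frame")
  out
}

#' Write feature frames to CSV
#' @param features a `feature_frames` data.frame from [compute_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_frames"))
  out <- data.table::data.table(
    t_s = features$t, sd_long_g = features$sd_long,
    sd_ap_g = features$sd_ap, sd_lat_g = features$sd_lat,
    sd_max_g = features$sd_max, inc_deg = features$inc_deg,
    theta_deg = features$theta_deg,
    flag_undefined = as.integer(features$flag_undefined))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}
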