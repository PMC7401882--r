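# Shared fixtures and independent oracles for the suite. Oracles here are
# deliberately naive re-implementations (loops, direct formulas) kept
# separate from the package's vectorized paths.

# One feature frame with every column classify_frames() consumes.
frame_row <- function(sd_long = 0, sd_max = sd_long, inc = 0, theta = 0) {
  data.frame(sd_long = sd_long, sd_max = sd_max, inc_deg = inc,
             theta_deg = theta)
}

# Naive per-window feature recomputation straight from the definitions:
# population SD per axis, angles from the window-mean vector.
oracle_features <- function(samples, fs, win_s = 2, overlap = 0.5) {
  w <- as.integer(win_s * fs)
  h <- as.integer(w * (1 - overlap))
  starts <- seq(1L, nrow(samples) - w + 1L, by = h)
  do.call(rbind, lapply(starts, function(s) {
    win <- samples[s:(s + w - 1L), , drop = FALSE]
    mu <- colMeans(win)
    sds <- apply(win, 2L, function(v) sqrt(mean((v - mean(v))^2)))
    nm <- sqrt(sum(mu^2))
    undef <- nm < 0.1
    data.frame(
      t = (s - 1 + w / 2) / fs,
      sd_long = sds[1L], sd_ap = sds[2L], sd_lat = sds[3L],
      sd_max = max(sds),
      inc_deg = if (undef) 0 else acos(max(-1, min(1, mu[1L] / nm))) * 180 / pi,
      theta_deg = if (undef) 0 else asin(max(-1, min(1, mu[2L] / nm))) * 180 / pi,
      flag_undefined = undef, row.names = NULL)
  }))
}

# Rule-by-rule decision-tree oracle, one frame at a time.
oracle_tree <- function(f, th) {
  if (f$sd_long > th$sd_move) {
    if (f$theta_deg > th$theta_bike) return("bike")
    if (f$sd_long > th$sd_run) return("run")
    return("walk")
  }
  if (f$inc_deg > th$inc_sit) return("sit")
  if (f$sd_max > th$sd_still) return("move")
  "stand"
}

# Direct shrinking-window binary median, recomputed by loop.
oracle_binary_median <- function(x, window_s) {
  half <- (window_s - 1L) %/% 2L
  n <- length(x)
  sapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    median(x[(i - h):(i + h)])
  })
}

# Bisect a scalar feature until the tree label flips; returns the
# boundary location. `make_frame(v)` builds the frame at feature value v.
bisect_boundary <- function(make_frame, th, lo, hi, iters = 60L) {
  lab_lo <- classify_frames(make_frame(lo), th)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (classify_frames(make_frame(mid), th) == lab_lo) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

# Random canonical recording with a plausible gravity component.
random_recording <- function(n = 300, fs = 30, seed = 1) {
  set.seed(seed)
  pitch <- runif(1, 0, 90) * pi / 180
  base <- cbind(cos(pitch), sin(pitch), 0)[rep(1, n), ]
  triaxial_recording(base + matrix(rnorm(3 * n, sd = 0.15), n, 3),
                     fs = fs, frame = "canonical")
}
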