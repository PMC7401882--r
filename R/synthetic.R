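#' Synthetic static-posture recording
#'
#' Kinematic generator: gravity projected onto the canonical axes for a
#' thigh held at a fixed sagittal pitch, plus independent zero-mean
#' Gaussian noise per axis. The expected window inclination equals
#' `pitch_deg` (0 = upright standing, ~85 = sitting with a near-horizontal
#' thigh); raising `lateral_noise_sd` while keeping the posture upright
#' reproduces the shuffling/"moving" region (high `sd_max`, low
#' `sd_long`).
#'
#' @param pitch_deg mean sagittal thigh pitch from vertical, degrees in
#'   `[0, 180]`.
#' @param noise_sd per-axis white-noise SD in g (longitudinal and
#'   anterior).
#' @param duration length in seconds.
#' @param fs sampling frequency in Hz (default 30).
#' @param lateral_noise_sd lateral-axis noise SD in g (defaults to
#'   `noise_sd`).
#' @param seed integer seed; `NULL` uses (and advances) no RNG stream
#'   only when `noise_sd = lateral_noise_sd = 0`.
#' @return A canonical-frame [triaxial_recording()].
#' @examples
#' gen_static(pitch_deg = 85, noise_sd = 0.02, duration = 10, fs = 30,
#'            seed = 1)
#' @export
gen_static <- function(pitch_deg, noise_sd, duration, fs = 30,
                       lateral_noise_sd = noise_sd, seed = 1) {
  if (pitch_deg < 0 || pitch_deg > 180) {
    stop("`pitch_deg` must lie in [0, 180] degrees")
  }
  n <- round(duration * fs)
  p <- pitch_deg * pi / 180
  base <- cbind(rep(cos(p), n), rep(sin(p), n), rep(0, n))
  noise <- with_rng(seed, matrix(stats::rnorm(3L * n), n, 3L)) %*%
    diag(c(noise_sd, noise_sd, lateral_noise_sd))
  triaxial_recording(base + noise, fs = fs, frame = "canonical")
}

#' Synthetic gait (walking/running) recording
#'
#' Pendular thigh pitch `phi(t) = swing_amp * sin(2 * pi * cadence * t)`
#' about vertical, with gravity projected onto the longitudinal and
#' anterior axes, plus white impact noise calibrated so the realized
#' per-window `sd_long` lands within 10% of `target_sd_long`. Because the
#' pitch oscillates symmetrically about vertical, the mean
#' forward/backward angle stays near zero — the signature that keeps gait
#' on the locomotion side of the biking node.
#'
#' @param swing_amp_deg pitch oscillation amplitude, degrees (> 0).
#' @param cadence stride frequency in Hz (> 0).
#' @param target_sd_long realized longitudinal SD to calibrate to, g
#'   (> 0.1, the dynamic-branch floor).
#' @param duration length in seconds.
#' @param fs sampling frequency in Hz (default 30).
#' @param seed integer seed.
#' @return A canonical-frame [triaxial_recording()].
#' @export
gen_locomotion <- function(swing_amp_deg, cadence, target_sd_long, duration,
                           fs = 30, seed = 1) {
  if (target_sd_long <= 0.1) {
    stop("`target_sd_long` must exceed the 0.1 g dynamic-branch floor")
  }
  if (swing_amp_deg <= 0 || cadence <= 0) {
    stop("calibration error: gait needs nonzero swing and cadence ",
         "(a static signal cannot realize a locomotion target)")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  phi <- swing_amp_deg * pi / 180 * sin(2 * pi * cadence * t)
  base_var <- mean_window_var(cos(phi), fs)
  if (base_var > target_sd_long^2) {
    stop("calibration error: pitch oscillation alone gives sd_long ",
         signif(sqrt(base_var), 3), " g, above the ", target_sd_long,
         " g target; reduce swing_amp_deg")
  }
  noise_sd <- sqrt(target_sd_long^2 - base_var)
  noise <- impact_noise(n, fs, cadence, noise_sd * c(1, 0.5, 0.5), seed)
  base <- cbind(cos(phi), sin(phi), rep(0, n))
  triaxial_recording(base + noise, fs = fs, frame = "canonical")
}

# Band-limited "impact" noise: equal-amplitude harmonics of the cadence
# (2nd upward, capped below 12 Hz, safely inside the passband of the
# 30 Hz working rate) with random phases per axis. Band-limiting keeps the calibrated
# window SD intact through anti-aliased resampling from the field rate,
# unlike white noise whose out-of-band power the filter would remove.
impact_noise <- function(n, fs, cadence, sd3, seed) {
  t <- (seq_len(n) - 1) / fs
  freqs <- cadence * (2:12)
  freqs <- freqs[freqs < 12]
  if (!length(freqs)) freqs <- 12 / (2:4)
  k <- length(freqs)
  phases <- with_rng(seed, matrix(stats::runif(3L * k, 0, 2 * pi), k, 3L))
  sapply(1:3, function(ax) {
    a <- sd3[ax] * sqrt(2 / k)
    rowSums(vapply(seq_len(k),
                   function(j) a * sin(2 * pi * freqs[j] * t + phases[j, ax]),
                   numeric(n)))
  })
}

# Mean within-window population variance of a deterministic signal under
# the standard 2-s/50%-overlap plan; used to budget the additive noise.
mean_window_var <- function(x, fs, win_s = 2, overlap = 0.5) {
  plan <- window_plan(length(x), fs, win_s = win_s, overlap = overlap)
  v <- vapply(seq_len(nrow(plan)), function(i) {
    w <- x[plan$start[i]:plan$end[i]]
    mean((w - mean(w))^2)
  }, numeric(1))
  mean(v)
}

#' Synthetic seated-pedalling (biking) recording
#'
#' The thigh pitch oscillates `swing_amp_deg` degrees (default 15) around
#' the forward saddle pitch at the pedalling cadence. The persistent
#' forward pitch keeps the window-mean forward/backward angle near
#' `saddle_pitch_deg` — the feature the biking node keys on — while the
#' oscillation plus impact noise keeps `sd_long` above the dynamic-branch
#' floor. A shallow saddle pitch (e.g. 10 degrees, as on a pedal-less
#' running bike pushed with the feet) produces gait-like frames that fall
#' on the locomotion side instead.
#'
#' @param saddle_pitch_deg mean forward thigh pitch while seated, degrees
#'   (> 0).
#' @param cadence pedalling frequency in Hz (> 0).
#' @param duration length in seconds.
#' @param fs sampling frequency in Hz (default 30).
#' @param swing_amp_deg pitch oscillation amplitude, degrees (default 15).
#' @param noise_sd white-noise SD on the longitudinal axis in g (default
#'   0.12; anterior and lateral get half).
#' @param seed integer seed.
#' @return A canonical-frame [triaxial_recording()].
#' @export
gen_biking <- function(saddle_pitch_deg, cadence, duration, fs = 30,
                       swing_amp_deg = 15, noise_sd = 0.12, seed = 1) {
  if (saddle_pitch_deg <= 0) stop("`saddle_pitch_deg` must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  phi <- (saddle_pitch_deg +
            swing_amp_deg * sin(2 * pi * cadence * t)) * pi / 180
  base <- cbind(cos(phi), sin(phi), rep(0, n))
  noise <- impact_noise(n, fs, cadence, noise_sd * c(1, 0.5, 0.5), seed)
  triaxial_recording(base + noise, fs = fs, frame = "canonical")
}

#' Declare one protocol activity scenario
#'
#' @param label activity name recorded in the ground-truth log.
#' @param type generator: `"static"`, `"locomotion"`, `"biking"` or
#'   `"mixture"` (playground-style alternation of short walk/run/stand
#'   segments).
#' @param duration scenario length in seconds.
#' @param trunk_pitch_deg back inclination used when a trunk recording is
#'   generated (degrees from vertical; default 15).
#' @param ... parameters forwarded to the generator (`pitch_deg`,
#'   `noise_sd`, `lateral_noise_sd`; `swing_amp_deg`, `cadence`,
#'   `target_sd_long`; `saddle_pitch_deg`, ...).
#' @return An object of class `activity_scenario`.
#' @export
scenario <- function(label, type = c("static", "locomotion", "biking",
                                     "mixture"),
                     duration, trunk_pitch_deg = 15, ...) {
  type <- match.arg(type)
  if (duration <= 0) stop("scenario duration must be positive")
  structure(list(label = label, type = type, duration = duration,
                 trunk_pitch_deg = trunk_pitch_deg, params = list(...)),
            class = "activity_scenario")
}

#' Declare a full synthetic protocol
#'
#' @param scenarios list of [scenario()] objects, performed in order.
#' @param gap_s unlabelled quiet-standing gap between consecutive
#'   scenarios, seconds (default 5).
#' @param seed integer seed driving all randomness of the protocol.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(scenarios, gap_s = 5, seed = 1) {
  if (!length(scenarios) ||
      !all(vapply(scenarios, inherits, logical(1), "activity_scenario"))) {
    stop("`scenarios` must be a non-empty list of scenario() objects")
  }
  if (gap_s < 0) stop("`gap_s` must be non-negative")
  structure(list(scenarios = scenarios, gap_s = gap_s,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Structured-protocol preset
#'
#' A bundled protocol emulating a supervised school/preschool activity
#' session: floor sitting, seated play, standing play, slow walking, brisk
#' walking, running, a playground-style mixture, biking, and sitting
#' again, in that order. Durations default to 90 s per activity (the
#' short, preschool-feasible end of the 1.5-5 min range such protocols
#' use) with 5-s breaks.
#'
#' @param duration_s seconds per activity (default 90).
#' @param gap_s seconds between activities (default 5).
#' @param seed integer seed.
#' @return A [protocol_spec()].
#' @export
table_protocol <- function(duration_s = 90, gap_s = 5, seed = 1) {
  protocol_spec(list(
    scenario("sit", "static", duration_s, trunk_pitch_deg = 20,
             pitch_deg = 85, noise_sd = 0.015),
    scenario("sit", "static", duration_s, trunk_pitch_deg = 15,
             pitch_deg = 78, noise_sd = 0.03),
    scenario("stand", "static", duration_s, trunk_pitch_deg = 5,
             pitch_deg = 8, noise_sd = 0.02, lateral_noise_sd = 0.04),
    scenario("walk", "locomotion", duration_s, trunk_pitch_deg = 8,
             swing_amp_deg = 20, cadence = 0.9, target_sd_long = 0.3),
    scenario("walk", "locomotion", duration_s, trunk_pitch_deg = 8,
             swing_amp_deg = 25, cadence = 1.1, target_sd_long = 0.5),
    scenario("run", "locomotion", duration_s, trunk_pitch_deg = 10,
             swing_amp_deg = 35, cadence = 1.4, target_sd_long = 0.9),
    scenario("playground", "mixture", duration_s, trunk_pitch_deg = 10),
    scenario("bike", "biking", duration_s, trunk_pitch_deg = 15,
             saddle_pitch_deg = 45, cadence = 1.2),
    scenario("sit", "static", duration_s, trunk_pitch_deg = 20,
             pitch_deg = 85, noise_sd = 0.015)
  ), gap_s = gap_s, seed = seed)
}

gen_scenario <- function(sc, fs, seed) {
  p <- sc$params
  switch(sc$type,
    static = do.call(gen_static,
                     c(list(duration = sc$duration, fs = fs, seed = seed), p)),
    locomotion = do.call(gen_locomotion,
                         c(list(duration = sc$duration, fs = fs,
                                seed = seed), p)),
    biking = do.call(gen_biking,
                     c(list(duration = sc$duration, fs = fs, seed = seed), p)),
    mixture = gen_mixture(sc$duration, fs, seed))
}

# Playground-style mixture: short (6-12 s) segments cycling through brisk
# walking, running, standing and shuffling.
gen_mixture <- function(duration, fs, seed) {
  segs <- list(
    function(d, s) gen_locomotion(25, 1.1, 0.45, d, fs, seed = s),
    function(d, s) gen_locomotion(35, 1.4, 0.85, d, fs, seed = s),
    function(d, s) gen_static(8, 0.02, d, fs, seed = s),
    function(d, s) gen_static(8, 0.03, d, fs, lateral_noise_sd = 0.25,
                              seed = s))
  lens <- with_rng(seed, {
    out <- numeric(0)
    while (sum(out) < duration) out <- c(out, sample(6:12, 1L))
    out
  })
  lens[length(lens)] <- duration - sum(lens[-length(lens)])
  lens <- lens[lens > 0]
  parts <- lapply(seq_along(lens), function(i) {
    segs[[((i - 1L) %% length(segs)) + 1L]](lens[i], seed + 7919L * i)
  })
  triaxial_recording(do.call(rbind, lapply(parts, `[[`, "samples")),
                     fs = fs, frame = "canonical")
}

#' Generate a full labelled protocol
#'
#' Concatenates the scenario signals with quiet-standing gaps, producing a
#' thigh recording, a ground-truth activity log whose entries coincide
#' exactly with the scenario boundaries, and optionally a time-aligned
#' trunk recording (static back pitch per scenario) for lying detection.
#' Deterministic for a given `spec$seed`.
#'
#' @param spec a [protocol_spec()].
#' @param fs sampling frequency in Hz (default 100, the field rate;
#'   the classification pipeline resamples to 30 Hz).
#' @param trunk also generate a trunk recording (default `FALSE`).
#' @return A list with elements `recording` (canonical
#'   [triaxial_recording()]), `log` ([activity_log()]) and `trunk`
#'   (recording or `NULL`).
#' @examples
#' out <- gen_protocol(table_protocol(duration_s = 30, seed = 7), fs = 30)
#' out$log
#' @export
gen_protocol <- function(spec, fs = 100, trunk = FALSE) {
  stopifnot(inherits(spec, "protocol_spec"))
  n_sc <- length(spec$scenarios)
  seeds <- (spec$seed %% 100000L) * 10000L + seq_len(2L * n_sc + 2L)
  parts <- list(); trunk_parts <- list()
  labels <- character(0); starts <- numeric(0); ends <- numeric(0)
  t_cur <- 0
  gap_rec <- function(s) gen_static(5, 0.02, spec$gap_s, fs, seed = s)
  for (i in seq_len(n_sc)) {
    sc <- spec$scenarios[[i]]
    parts[[length(parts) + 1L]] <- gen_scenario(sc, fs, seeds[2L * i - 1L])
    labels <- c(labels, sc$label)
    starts <- c(starts, t_cur)
    ends <- c(ends, t_cur + sc$duration)
    if (trunk) {
      trunk_parts[[length(trunk_parts) + 1L]] <-
        gen_static(sc$trunk_pitch_deg, 0.02, sc$duration, fs,
                   seed = seeds[2L * i])
    }
    t_cur <- t_cur + sc$duration
    if (i < n_sc && spec$gap_s > 0) {
      parts[[length(parts) + 1L]] <- gap_rec(seeds[2L * n_sc + 1L] + i)
      if (trunk) {
        trunk_parts[[length(trunk_parts) + 1L]] <-
          gen_static(10, 0.02, spec$gap_s, fs,
                     seed = seeds[2L * n_sc + 2L] + i)
      }
      t_cur <- t_cur + spec$gap_s
    }
  }
  bind <- function(ps) triaxial_recording(
    do.call(rbind, lapply(ps, `[[`, "samples")), fs = fs,
    frame = "canonical")
  list(recording = bind(parts),
       log = activity_log(labels, starts, ends),
       trunk = if (trunk) bind(trunk_parts) else NULL)
}
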