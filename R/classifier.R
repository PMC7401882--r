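#' Activity label vocabulary
#'
#' The labels the classifier can emit, in decreasing resolution priority:
#' lying and sitting dominate everything, biking dominates locomotion, and
#' locomotion dominates stand/move. `"undefined"` marks seconds with no
#' surviving assignment after smoothing.
#'
#' @return Character vector of the eight labels.
#' @export
activity_labels <- function() {
  c("lie", "sit", "bike", "walk", "run", "stand", "move", "undefined")
}

#' Decision-tree threshold set
#'
#' The five decision-node constants plus the trunk back-angle used for
#' lying detection. Two immutable presets are shipped:
#' \describe{
#'   \item{`child`}{`sd_move` 0.1 g, `theta_bike` 22.5 deg, `sd_run`
#'     0.65 g, `inc_sit` 47.5 deg, `sd_still` 0.13 g, `back_lie` 65 deg —
#'     calibrated on preschoolers, children and adolescents;}
#'   \item{`adult`}{`sd_move` 0.1 g, `theta_bike` 24 deg, `sd_run`
#'     0.72 g, `inc_sit` 45 deg, `sd_still` 0.1 g, `back_lie` 65 deg —
#'     the original adult calibration.}
#' }
#' Any field can be overridden individually.
#'
#' @param preset `"child"` (default) or `"adult"`.
#' @param ... named numeric overrides for individual fields
#'   (`sd_move`, `theta_bike`, `sd_run`, `inc_sit`, `sd_still`,
#'   `back_lie`).
#' @return An object of class `threshold_set`.
#' @examples
#' thresholds("child")
#' thresholds("adult", theta_bike = 25)
#' @export
thresholds <- function(preset = c("child", "adult"), ...) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) stop("unknown threshold preset: ",
                                              preset[1L]))
  th <- switch(preset,
    child = list(sd_move = 0.1, theta_bike = 22.5, sd_run = 0.65,
                 inc_sit = 47.5, sd_still = 0.13, back_lie = 65),
    adult = list(sd_move = 0.1, theta_bike = 24, sd_run = 0.72,
                 inc_sit = 45, sd_still = 0.1, back_lie = 65))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(th))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown threshold fields: ", paste(bad, collapse = ", "))
    }
    th[names(over)] <- lapply(over, as.numeric)
  }
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  if (th$sd_run <= th$sd_move) {
    stop("sd_run must exceed sd_move (walk/run split above the movement root)")
  }
  structure(c(th, list(preset = preset)), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set> %s: sd_move %g g, theta_bike %g deg, ",
                     "sd_run %g g, inc_sit %g deg, sd_still %g g, ",
                     "back_lie %g deg\n"),
              x$preset, x$sd_move, x$theta_bike, x$sd_run, x$inc_sit,
              x$sd_still, x$back_lie))
  invisible(x)
}

#' Classify feature frames with the decision tree
#'
#' Five strict-greater-than conditions identify six activity types.
#' Root: `sd_long > sd_move` selects the dynamic branch, where
#' `theta_deg > theta_bike` gives biking and otherwise
#' `sd_long > sd_run` splits running from walking. On the stationary
#' branch, `inc_deg > inc_sit` gives sitting and otherwise
#' `sd_max > sd_still` splits moving/shuffling from standing still.
#' Equality at any node takes the false branch.
#'
#' @param features a `feature_frames` data.frame from
#'   [compute_features()], or any data.frame with columns `sd_long`,
#'   `sd_max`, `inc_deg`, `theta_deg`.
#' @param th a [thresholds()] set.
#' @return Character vector of labels, one per frame, each in
#'   `c("sit", "stand", "move", "walk", "run", "bike")`.
#' @examples
#' f <- data.frame(sd_long = 0.3, sd_max = 0.35, inc_deg = 20,
#'                 theta_deg = 40)
#' classify_frames(f, thresholds("child"))   # bike
#' @export
classify_frames <- function(features, th) {
  stopifnot(inherits(th, "threshold_set"))
  need <- c("sd_long", "sd_max", "inc_deg", "theta_deg")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features lack columns: ", paste(miss, collapse = ", "))
  dynamic <- features$sd_long > th$sd_move
  out <- ifelse(dynamic,
                ifelse(features$theta_deg > th$theta_bike, "bike",
                       ifelse(features$sd_long > th$sd_run, "run", "walk")),
                ifelse(features$inc_deg > th$inc_sit, "sit",
                       ifelse(features$sd_max > th$sd_still, "move", "stand")))
  as.character(out)
}

#' Per-second label series
#'
#' @param labels character vector, one label per second, values from
#'   [activity_labels()].
#' @param t0 time of the first labelled second (s); defaults to 1 (centre
#'   of the first 2-s window).
#' @param flags optional logical vector marking unreliable seconds.
#' @return An object of class `label_series`.
#' @export
label_series <- function(labels, t0 = 1, flags = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), activity_labels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (is.null(flags)) flags <- rep(FALSE, length(labels))
  stopifnot(length(flags) == length(labels))
  structure(list(labels = labels, t0 = as.numeric(t0),
                 flags = as.logical(flags)),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_series> %d s from t0 = %g s: %s\n",
              length(x$labels), x$t0,
              paste(names(tab), as.integer(tab), sep = ":", collapse = " ")))
  invisible(x)
}

#' @export
length.label_series <- function(x) length(x$labels)

#' Smoothing configuration for the label stream
#'
#' @param mode `"per_activity_median"` (default; the binary indicator
#'   stream of every activity is median-filtered separately, which can
#'   assert several activities for one second — resolved afterwards by
#'   [resolve_multilabel()]), `"majority"` (sliding modal label) or
#'   `"none"`.
#' @param window_s filter window in seconds; odd positive integer
#'   (default 5).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(mode = c("per_activity_median", "majority",
                                      "none"),
                             window_s = 5) {
  mode <- match.arg(mode)
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s < 1 ||
      window_s != round(window_s) || window_s %% 2 == 0) {
    stop("`window_s` must be an odd positive integer (seconds)")
  }
  structure(list(mode = mode, window_s = as.integer(window_s)),
            class = "smoothing_config")
}

#' Smooth a per-second label series
#'
#' Removes sporadic single-second misclassifications. In
#' `per_activity_median` mode each activity's 0/1 indicator stream is
#' median-filtered with the configured window (shrinking symmetric windows
#' at the edges); a second may then be asserted by zero, one or several
#' activities, returned as the `assigned` attribute (a logical matrix) for
#' [resolve_multilabel()], together with each activity's local support
#' (windowed indicator mean, used for the walk-vs-run tie rule). In
#' `majority` mode the modal label of the sliding window is taken, ties
#' broken in favour of the centre label, then by the [activity_labels()]
#' priority order. `none` returns the input.
#'
#' @param series a [label_series()].
#' @param cfg a [smoothing_config()].
#' @return A [label_series()]; in `per_activity_median` mode with
#'   attributes `assigned` (n x activity logical matrix) and `support`
#'   (matching numeric matrix). Seconds asserted by no activity are
#'   labelled `"undefined"` until resolution.
#' @export
smooth_labels <- function(series, cfg = smoothing_config()) {
  stopifnot(inherits(series, "label_series"),
            inherits(cfg, "smoothing_config"))
  labs <- series$labels
  n <- length(labs)
  if (cfg$mode == "none" || n == 0L) return(series)
  half <- (cfg$window_s - 1L) %/% 2L
  if (cfg$mode == "majority") {
    prio <- activity_labels()
    out <- vapply(seq_len(n), function(i) {
      h <- min(half, i - 1L, n - i)        # shrunken symmetric edge window
      w <- labs[(i - h):(i + h)]
      tab <- table(w)
      top <- names(tab)[tab == max(tab)]
      if (labs[i] %in% top) labs[i] else top[order(match(top, prio))][1L]
    }, character(1))
    return(label_series(out, t0 = series$t0, flags = series$flags))
  }
  acts <- intersect(activity_labels(), unique(labs))
  assigned <- matrix(FALSE, n, length(acts), dimnames = list(NULL, acts))
  support <- matrix(0, n, length(acts), dimnames = list(NULL, acts))
  for (a in acts) {
    ind <- as.numeric(labs == a)
    assigned[, a] <- shrinking_median(ind, half) > 0.5
    support[, a] <- shrinking_mean(ind, half)
  }
  out <- apply_priority(assigned, support)
  res <- label_series(out, t0 = series$t0, flags = series$flags)
  attr(res, "assigned") <- assigned
  attr(res, "support") <- support
  res
}

# Median over symmetric windows that shrink near the edges (the window at
# position i spans i +/- min(half, distance to nearer edge)).
shrinking_median <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(x[(i - h):(i + h)])
  }, numeric(1))
}

shrinking_mean <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Resolve multiple per-second activity assignments
#'
#' Per-activity median filtering can assert several activities for the
#' same second; multiple assignments are not permitted in the output and
#' are reduced by priority: if lying or sitting is asserted any other
#' activity is removed; if biking is asserted together with others, biking
#' is selected; walking or running beats standing or moving. When both
#' walking and running survive, the one with the larger local support
#' wins, ties going to walking. A second asserted by no activity becomes
#' `"undefined"`.
#'
#' @param assigned logical matrix (seconds x activities, named columns) of
#'   asserted activities, e.g. the `assigned` attribute of
#'   [smooth_labels()].
#' @param support optional matching numeric matrix of local support used
#'   only for the walk-vs-run tie; defaults to all-equal support.
#' @param t0 time of the first second (s).
#' @return A [label_series()].
#' @export
resolve_multilabel <- function(assigned, support = NULL, t0 = 1) {
  assigned <- as.matrix(assigned)
  if (is.null(colnames(assigned))) stop("`assigned` needs activity colnames")
  if (is.null(support)) {
    support <- matrix(1, nrow(assigned), ncol(assigned),
                      dimnames = dimnames(assigned))
  }
  label_series(apply_priority(assigned, support), t0 = t0)
}

apply_priority <- function(assigned, support) {
  n <- nrow(assigned)
  acts <- colnames(assigned)
  has <- function(a) if (a %in% acts) assigned[, a] else rep(FALSE, n)
  sup <- function(a) if (a %in% acts) support[, a] else rep(0, n)
  out <- rep("undefined", n)
  out[has("move")] <- "move"
  out[has("stand")] <- "stand"
  # walk/run dominate stand/move; mutual conflict decided by local support
  walk <- has("walk"); run <- has("run")
  both <- walk & run
  out[walk & !both] <- "walk"
  out[run & !both] <- "run"
  out[both] <- ifelse(sup("run")[both] > sup("walk")[both], "run", "walk")
  out[has("bike")] <- "bike"
  out[has("sit")] <- "sit"
  out[has("lie")] <- "lie"
  out
}

#' Relabel sitting seconds as lying using a trunk sensor
#'
#' A second classified as sitting from the thigh is relabelled lying when
#' the trunk (back) inclination for that second exceeds the `back_lie`
#' threshold (strictly greater than 65 degrees by default). All other
#' seconds are unchanged; without a trunk recording the pipeline never
#' emits a lying label.
#'
#' @param thigh a [label_series()] from the thigh pipeline.
#' @param trunk_features `feature_frames` for the trunk recording on the
#'   same 1-s grid (equal length, same `t0`).
#' @param th a [thresholds()] set.
#' @return The relabelled [label_series()].
#' @export
detect_lying <- function(thigh, trunk_features, th = thresholds("child")) {
  stopifnot(inherits(thigh, "label_series"),
            inherits(th, "threshold_set"))
  if (nrow(trunk_features) != length(thigh$labels)) {
    stop("trunk features (", nrow(trunk_features),
         " s) are not aligned with thigh labels (",
         length(thigh$labels), " s)")
  }
  labs <- thigh$labels
  labs[labs == "sit" & trunk_features$inc_deg > th$back_lie] <- "lie"
  label_series(labs, t0 = thigh$t0, flags = thigh$flags)
}

#' Classify a raw recording end to end
#'
#' Composition of the full pipeline: orientation remap to the canonical
#' frame (skipped when the recording is already canonical), resampling to
#' the 30 Hz working rate, 2-s/50%-overlap feature extraction, decision
#' tree, label smoothing and priority resolution, and — when a trunk
#' recording is supplied — lying detection.
#'
#' @param rec a [triaxial_recording()] at any rate >= 30 Hz.
#' @param orientation a [device_orientation()]; required when `rec` is in
#'   the raw device frame.
#' @param th a [thresholds()] set (default child preset).
#' @param cfg a [smoothing_config()].
#' @param trunk optional trunk [triaxial_recording()] (canonical or with
#'   the same orientation) for lying detection.
#' @param target_fs working rate (default 30 Hz).
#' @return A [label_series()] with one label per second.
#' @examples
#' rec <- gen_static(pitch_deg = 85, noise_sd = 0.02, duration = 30,
#'                   fs = 30, seed = 1)
#' classify_recording(rec)   # sitting
#' @export
classify_recording <- function(rec, orientation = NULL,
                               th = thresholds("child"),
                               cfg = smoothing_config(),
                               trunk = NULL, target_fs = 30) {
  stopifnot(inherits(rec, "triaxial_recording"))
  prep <- function(r) {
    if (r$frame == "raw_device") {
      if (is.null(orientation)) {
        stop("raw-device recording needs a device_orientation")
      }
      r <- remap_to_canonical(r, orientation)
    }
    if (r$fs != target_fs) r <- resample_recording(r, target_fs)
    r
  }
  feats <- compute_features(prep(rec), fs_expected = target_fs)
  raw <- label_series(classify_frames(feats, th), t0 = feats$t[1L],
                      flags = feats$flag_undefined)
  out <- smooth_labels(raw, cfg)
  if (!is.null(trunk)) {
    tf <- compute_features(prep(trunk), fs_expected = target_fs)
    k <- min(nrow(tf), length(out$labels))
    if (k < length(out$labels)) {
      stop("trunk recording shorter than thigh recording; cannot align")
    }
    out <- detect_lying(out, tf[seq_len(length(out$labels)), ], th)
  }
  out
}

#' Write a label series to CSV
#' @param series a [label_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(series, path) {
  stopifnot(inherits(series, "label_series"))
  data.table::fwrite(
    data.table::data.table(second_index = seq_along(series$labels) - 1L,
                           t_s = series$t0 + seq_along(series$labels) - 1L,
                           label = series$labels,
                           flag = as.integer(series$flags)),
    path, quote = FALSE)
  invisible(path)
}

#' Read a label series from CSV written by [write_labels()]
#' @param path path to the label CSV.
#' @return A [label_series()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  if (!all(c("t_s", "label") %in% names(dt))) {
    stop("label file '", path, "' lacks t_s/label columns")
  }
  flags <- if ("flag" %in% names(dt)) as.logical(dt$flag) else NULL
  label_series(dt$label, t0 = dt$t_s[1L], flags = flags)
}
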