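#' Align predicted labels with an activity log
#'
#' Produces one (truth, predicted) pair per labelled second whose time
#' falls inside a log interval, after optionally discarding a lead-in (and
#' a tail) from every interval. Seconds outside any interval are excluded,
#' so protocol gaps and transitions never enter the tabulation.
#'
#' @param pred a [label_series()].
#' @param log an [activity_log()] in recording-relative seconds.
#' @param lead_in seconds discarded at the start of every interval
#'   (default 0).
#' @param tail seconds discarded at the end of every interval (default 0;
#'   set both to the window width to score interior seconds only).
#' @return A data.frame with columns `t`, `truth`, `pred`.
#' @export
align_labels <- function(pred, log, lead_in = 0, tail = 0) {
  stopifnot(inherits(pred, "label_series"), inherits(log, "activity_log"))
  t <- pred$t0 + seq_along(pred$labels) - 1
  truth <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(log))) {
    inside <- t >= log$start[i] + lead_in & t < log$end[i] - tail
    truth[inside] <- log$label[i]
  }
  keep <- !is.na(truth)
  if (!any(keep)) {
    stop("no labelled second falls inside any log interval; ",
         "prediction spans [", min(t), ", ", max(t), "] s")
  }
  data.frame(t = t[keep], truth = truth[keep], pred = pred$labels[keep],
             stringsAsFactors = FALSE)
}

#' Per-activity sensitivity and specificity
#'
#' One-vs-rest confusion counts over second-by-second (truth, predicted)
#' pairs, for every activity present in either stream. Sensitivity is
#' `100 * TP / (TP + FN)` and specificity `100 * TN / (TN + FP)`, reported
#' to one decimal. A predicted `"undefined"` second counts as a negative
#' prediction for every activity, penalizing sensitivity but never
#' specificity.
#'
#' @param pairs data.frame with columns `truth` and `pred`, e.g. from
#'   [align_labels()].
#' @return An object of class `confusion_summary`: a data.frame with one
#'   row per activity and columns `activity`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`.
#' @examples
#' pairs <- data.frame(truth = rep("walk", 100),
#'                     pred = rep(c("walk", "run"), c(90, 10)))
#' confusion(pairs)
#' @export
confusion <- function(pairs) {
  if (nrow(pairs) < 1L) stop("need at least one (truth, predicted) pair")
  acts <- setdiff(union(pairs$truth, pairs$pred), "undefined")
  acts <- acts[order(match(acts, activity_labels(), nomatch = 99L))]
  rows <- lapply(acts, function(a) {
    tp <- sum(pairs$truth == a & pairs$pred == a)
    fn <- sum(pairs$truth == a & pairs$pred != a)
    fp <- sum(pairs$truth != a & pairs$pred == a)
    tn <- sum(pairs$truth != a & pairs$pred != a)
    data.frame(activity = a, tp = tp, fn = fn, tn = tn, fp = fp,
               sensitivity = round(100 * tp / (tp + fn), 1),
               specificity = round(100 * tn / (tn + fp), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_summary", "data.frame")
  out
}

#' Predicted-label composition of a logged activity
#'
#' For complex activities without a single expected label (ball games,
#' playground circuits, swings), reports what fraction of the activity's
#' seconds each predicted label received.
#'
#' @param pred a [label_series()].
#' @param log an [activity_log()].
#' @param activity activity name to look up in the log.
#' @param lead_in,tail per-interval trimming as in [align_labels()].
#' @return A data.frame with columns `label` and `percent` (1 decimal,
#'   summing to 100 up to rounding), sorted by decreasing share.
#' @export
composition <- function(pred, log, activity, lead_in = 0, tail = 0) {
  if (!activity %in% log$label) {
    stop("activity '", activity, "' not present in the log")
  }
  pairs <- align_labels(pred, log, lead_in = lead_in, tail = tail)
  sel <- pairs$pred[pairs$truth == activity]
  if (!length(sel)) stop("no scored seconds for activity '", activity, "'")
  tab <- sort(table(sel), decreasing = TRUE)
  data.frame(label = names(tab),
             percent = round(100 * as.numeric(tab) / length(sel), 1),
             stringsAsFactors = FALSE)
}

#' Pooled class-conditional feature densities and crossing candidates
#'
#' Gaussian-kernel density (rule-of-thumb bandwidth by default, matching a
#' stock density plot) of one feature pooled within each of two class
#' groupings, on a common grid, with the grid locations where the density
#' ordering flips reported as candidate thresholds. Candidates are an
#' exploration aid for visual threshold selection and are never applied
#' automatically.
#'
#' @param features a `feature_frames` data.frame carrying a `class` column
#'   (or supply `classes` as a vector of per-frame class names).
#' @param feature feature column to pool (`"sd_long"`, `"sd_max"`,
#'   `"inc_deg"` or `"theta_deg"`).
#' @param groups named list of two character vectors of class names
#'   defining the groupings, e.g.
#'   `list(stationary = c("sit", "stand"), dynamic = c("walk", "run"))`.
#' @param classes per-frame class labels when `features` has no `class`
#'   column.
#' @param bw bandwidth passed to [stats::density()] (default `"nrd0"`,
#'   the rule of thumb).
#' @param n grid size (default 512).
#' @return An object of class `density_pair`: a list with `feature`,
#'   `curves` (data.frame: `x`, `density`, `group`) and `crossings`
#'   (numeric vector of interpolated crossing locations).
#' @export
pooled_density <- function(features, feature, groups, classes = NULL,
                           bw = "nrd0", n = 512) {
  if (is.null(classes)) {
    if (!"class" %in% names(features)) {
      stop("supply `classes` or a `class` column on `features`")
    }
    classes <- features$class
  }
  if (length(groups) != 2L || is.null(names(groups))) {
    stop("`groups` must be a named list of exactly two class groupings")
  }
  x <- features[[feature]]
  if (is.null(x)) stop("unknown feature column: ", feature)
  vals <- lapply(groups, function(g) x[classes %in% g])
  sizes <- lengths(vals)
  if (any(sizes < 30L)) {
    stop("each class grouping needs >= 30 frames (got ",
         paste(sizes, collapse = ", "), ")")
  }
  if (any(vapply(vals, stats::sd, numeric(1)) == 0)) {
    stop("zero-variance class grouping: kernel density is degenerate, ",
         "inspect a histogram instead")
  }
  rng <- range(unlist(vals))
  pad <- 3 * max(vapply(vals, stats::bw.nrd0, numeric(1)))
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n)
  dens <- lapply(vals, function(v) {
    d <- stats::density(v, bw = bw, from = grid[1L], to = grid[n], n = n)
    d$y
  })
  # ordering flips of the density difference; stretches where both
  # densities are numerically zero (well-separated classes) count as part
  # of the transition, with the candidate placed mid-plateau
  d <- dens[[1L]] - dens[[2L]]
  s <- sign(d)
  s[abs(d) < 1e-12 * max(abs(d))] <- 0
  nz <- which(s != 0)
  crossings <- numeric(0)
  if (length(nz) > 1L) {
    for (j in seq_len(length(nz) - 1L)) {
      i1 <- nz[j]; i2 <- nz[j + 1L]
      if (s[i1] * s[i2] < 0) {
        crossings <- c(crossings, if (i2 == i1 + 1L) {
          grid[i1] + (grid[i2] - grid[i1]) * d[i1] / (d[i1] - d[i2])
        } else {
          (grid[i1] + grid[i2]) / 2     # midpoint of the zero plateau
        })
      }
    }
  }
  curves <- data.frame(
    x = rep(grid, 2L),
    density = c(dens[[1L]], dens[[2L]]),
    group = rep(names(groups), each = n), stringsAsFactors = FALSE)
  structure(list(feature = feature, curves = curves,
                 crossings = crossings),
            class = "density_pair")
}

#' @export
print.density_pair <- function(x, ...) {
  cat(sprintf("<density_pair> %s: crossings at %s\n", x$feature,
              paste(signif(x$crossings, 5), collapse = ", ")))
  invisible(x)
}

#' Write density curves to CSV
#' @param dp a `density_pair` from [pooled_density()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(dp, path) {
  stopifnot(inherits(dp, "density_pair"))
  data.table::fwrite(dp$curves, path, quote = FALSE)
  invisible(path)
}

#' Stratified half split into development and validation groups
#'
#' Randomly assigns half of each age group to the development set and the
#' rest to validation; odd group counts give the extra subject to
#' development. Deterministic for a given seed.
#'
#' @param subjects data.frame with columns `id` and `group`.
#' @param seed integer seed.
#' @return A list with data.frames `development` and `validation`.
#' @export
split_subjects <- function(subjects, seed) {
  if (!all(c("id", "group") %in% names(subjects))) {
    stop("`subjects` needs columns id and group")
  }
  if (any(table(subjects$group) == 0L) || nrow(subjects) == 0L) {
    stop("every group must contain at least one subject")
  }
  dev_idx <- with_rng(seed, {
    unlist(lapply(split(seq_len(nrow(subjects)), subjects$group),
                  function(idx) {
                    k <- ceiling(length(idx) / 2)
                    if (length(idx) == 1L) idx else sample(idx, k)
                  }))
  })
  dev_idx <- sort(unname(dev_idx))
  list(development = subjects[dev_idx, , drop = FALSE],
       validation = subjects[setdiff(seq_len(nrow(subjects)), dev_idx), ,
                             drop = FALSE])
}

#' Write a confusion summary to JSON or CSV
#'
#' @param cs a `confusion_summary` from [confusion()].
#' @param path output path; `.json` gives a per-activity object keyed by
#'   activity name, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(cs, path) {
  stopifnot(inherits(cs, "confusion_summary"))
  if (grepl("\\.json$", path)) {
    obj <- lapply(seq_len(nrow(cs)), function(i) {
      as.list(cs[i, c("tp", "fn", "tn", "fp", "sensitivity",
                      "specificity")])
    })
    names(obj) <- cs$activity
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    data.table::fwrite(cs, path, quote = FALSE)
  }
  invisible(path)
}
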