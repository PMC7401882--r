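test_that("threshold presets carry the published constants", {
  child <- thresholds("child")
  expect_equal(child$sd_move, 0.1)
  expect_equal(child$theta_bike, 22.5)
  expect_equal(child$sd_run, 0.65)
  expect_equal(child$inc_sit, 47.5)
  expect_equal(child$sd_still, 0.13)
  expect_equal(child$back_lie, 65)

  adult <- thresholds("adult")
  # presets share the 0.1 g root and 65-degree lying rule and differ only
  # in the four recalibrated nodes
  expect_equal(adult$sd_move, child$sd_move)
  expect_equal(adult$back_lie, child$back_lie)
  expect_equal(adult$theta_bike, 24)
  expect_equal(adult$sd_run, 0.72)
  expect_equal(adult$inc_sit, 45)
  expect_equal(adult$sd_still, 0.1)

  expect_equal(thresholds("child", theta_bike = 30)$theta_bike, 30)
  expect_error(thresholds("child", banana = 1), "unknown threshold")
  expect_error(thresholds("teen"), "unknown threshold preset")
  expect_error(thresholds("child", sd_run = 0.05), "sd_run must exceed")
})

test_that("the tree routes canonical example frames correctly", {
  th <- thresholds("child")
  expect_equal(classify_frames(frame_row(0.02, 0.03, inc = 90), th), "sit")
  expect_equal(classify_frames(frame_row(0.3, theta = 40), th), "bike")
  expect_equal(classify_frames(frame_row(0.3, theta = 10), th), "walk")
  expect_equal(classify_frames(frame_row(0.8, theta = 0), th), "run")
  expect_equal(classify_frames(frame_row(0.5, theta = 0), th), "walk")
  expect_equal(classify_frames(frame_row(0.05, 0.2, inc = 10), th), "move")
  expect_equal(classify_frames(frame_row(0.05, 0.05, inc = 10), th),
               "stand")
})

test_that("equality at every node takes the false branch", {
  th <- thresholds("child")
  expect_equal(classify_frames(frame_row(0.1, 0.1, inc = 0), th), "stand")
  expect_equal(classify_frames(frame_row(0.3, theta = 22.5), th), "walk")
  expect_equal(classify_frames(frame_row(0.65, theta = 0), th), "walk")
  expect_equal(classify_frames(frame_row(0.02, 0.02, inc = 47.5), th),
               "stand")
  expect_equal(classify_frames(frame_row(0.05, 0.13, inc = 10), th),
               "stand")
})

test_that("a feature-space grid agrees with the rule-by-rule oracle", {
  for (preset in c("child", "adult")) {
    th <- thresholds(preset)
    grid <- expand.grid(sd_long = c(0.02, 0.09, 0.11, 0.3, 0.64, 0.66, 1.2),
                        inc = c(5, 40, 50, 90),
                        sd_max_extra = c(0, 0.05, 0.2),
                        theta = c(-10, 0, 20, 23, 30, 60))
    grid$sd_max <- grid$sd_long + grid$sd_max_extra
    f <- frame_row(grid$sd_long, grid$sd_max, grid$inc, grid$theta)
    got <- classify_frames(f, th)
    want <- vapply(seq_len(nrow(f)),
                   function(i) oracle_tree(f[i, ], th), character(1))
    expect_identical(got, want)
  }
})

test_that("decision-boundary bisection recovers every configured node", {
  th <- thresholds("child", theta_bike = 19.25, sd_run = 0.7,
                   inc_sit = 51, sd_still = 0.17, sd_move = 0.12)
  expect_equal(bisect_boundary(function(v) frame_row(v, v), th, 0, 0.3),
               0.12, tolerance = 1e-6)
  expect_equal(bisect_boundary(function(v) frame_row(0.3, theta = v),
                               th, 0, 60), 19.25, tolerance = 1e-6)
  expect_equal(bisect_boundary(function(v) frame_row(v, theta = 0),
                               th, 0.2, 1.5), 0.7, tolerance = 1e-6)
  expect_equal(bisect_boundary(function(v) frame_row(0.02, 0.02, inc = v),
                               th, 0, 90), 51, tolerance = 1e-6)
  expect_equal(bisect_boundary(function(v) frame_row(0.05, v, inc = 10),
                               th, 0.001, 0.5), 0.17, tolerance = 1e-6)
})

test_that("majority smoothing removes outliers and keeps constants", {
  s <- label_series(c("walk", "walk", "run", "walk", "walk"))
  out <- smooth_labels(s, smoothing_config("majority", 5))
  expect_equal(out$labels, rep("walk", 5))

  const <- label_series(rep("sit", 10))
  for (mode in c("majority", "per_activity_median", "none")) {
    expect_equal(smooth_labels(const, smoothing_config(mode, 5))$labels,
                 rep("sit", 10))
  }
  expect_error(smoothing_config("majority", 4), "odd")
})

test_that("per-activity median smoothing matches the binary oracle", {
  set.seed(21)
  labs <- sample(c("sit", "walk", "run", "stand"), 60, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  s <- label_series(labs)
  out <- smooth_labels(s, smoothing_config("per_activity_median", 5))
  assigned <- attr(out, "assigned")
  for (a in colnames(assigned)) {
    expect_equal(unname(assigned[, a]),
                 oracle_binary_median(as.numeric(labs == a), 5) > 0.5,
                 label = a)
  }
  # smoothing never asserts an activity absent from the window it covers
  for (i in seq_along(labs)) {
    win <- labs[max(1, i - 2):min(length(labs), i + 2)]
    expect_true(all(colnames(assigned)[assigned[i, ]] %in% win))
  }
})

test_that("priority rules resolve multiple assignments", {
  mk <- function(...) {
    acts <- c(...)
    m <- matrix(FALSE, 1, length(activity_labels()),
                dimnames = list(NULL, activity_labels()))
    m[1, acts] <- TRUE
    m
  }
  expect_equal(resolve_multilabel(mk("sit", "walk"))$labels, "sit")
  expect_equal(resolve_multilabel(mk("lie", "bike"))$labels, "lie")
  expect_equal(resolve_multilabel(mk("bike", "run"))$labels, "bike")
  expect_equal(resolve_multilabel(mk("walk", "stand"))$labels, "walk")
  expect_equal(resolve_multilabel(mk("run", "move"))$labels, "run")
  expect_equal(resolve_multilabel(mk())$labels, "undefined")
  # walk vs run: larger local support wins, ties to walk
  sup <- function(w, r) {
    m <- mk("walk", "run")
    s <- m * 0; s[1, "walk"] <- w; s[1, "run"] <- r
    resolve_multilabel(m, support = s)$labels
  }
  expect_equal(sup(0.6, 0.4), "walk")
  expect_equal(sup(0.2, 0.8), "run")
  expect_equal(sup(0.5, 0.5), "walk")
  # order independence: permuting columns never changes the outcome
  set.seed(3)
  for (i in 1:25) {
    acts <- sample(setdiff(activity_labels(), "undefined"),
                   sample(1:4, 1))
    m <- mk(acts)
    perm <- sample(ncol(m))
    expect_equal(resolve_multilabel(m[, perm, drop = FALSE])$labels,
                 resolve_multilabel(m)$labels)
  }
})

test_that("lying detection relabels sitting seconds only, strictly above 65", {
  th <- thresholds("child")
  thigh <- label_series(c("sit", "stand", "sit", "sit"))
  trunk <- data.frame(inc_deg = c(80, 80, 65, 50))
  out <- detect_lying(thigh, trunk, th)
  expect_equal(out$labels, c("lie", "stand", "sit", "sit"))
  expect_error(detect_lying(thigh, trunk[1:2, , drop = FALSE], th),
               "not aligned")
})

test_that("end-to-end classification is deterministic and orientation-invariant", {
  rec <- gen_static(85, 0.02, 40, fs = 100, seed = 12)
  out1 <- classify_recording(rec)
  expect_true(all(out1$labels == "sit"))
  expect_identical(classify_recording(rec)$labels, out1$labels)

  # the same physical signal seen through either mounting gives the same
  # labels once the orientation is declared
  for (preset in c("school", "preschool")) {
    orient <- device_orientation(preset)
    dev <- remap_to_device(rec, orient)
    expect_identical(classify_recording(dev, orientation = orient)$labels,
                     out1$labels)
  }

  # with no smoothing the pipeline equals frame-by-frame classification
  walkrec <- gen_locomotion(25, 1.1, 0.4, 30, fs = 30, seed = 4)
  feats <- compute_features(walkrec)
  expect_equal(
    classify_recording(walkrec, cfg = smoothing_config("none"))$labels,
    classify_frames(feats, thresholds("child")))
})
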