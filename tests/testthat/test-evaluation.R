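test_that("alignment pairs whole seconds inside log intervals", {
  pred <- label_series(rep("sit", 15), t0 = 1)
  log <- activity_log("sit", 0, 10)
  pairs <- align_labels(pred, log)
  expect_equal(nrow(pairs), 9)          # seconds 1..9 fall inside [0, 10)
  expect_true(all(pairs$truth == "sit" & pairs$pred == "sit"))

  expect_error(align_labels(pred, activity_log("sit", 100, 110)),
               "no labelled second")

  long_pred <- label_series(rep("walk", 320), t0 = 1)
  pairs <- align_labels(long_pred, activity_log("walk", 0, 300),
                        lead_in = 60)
  expect_equal(nrow(pairs), 240)
})

test_that("confusion counts give the textbook rates", {
  pairs <- data.frame(truth = rep("walk", 100),
                      pred = rep(c("walk", "run"), c(90, 10)))
  cs <- confusion(pairs)
  expect_equal(cs$sensitivity[cs$activity == "walk"], 90.0)
  expect_equal(cs$specificity[cs$activity == "run"], 90.0)

  perfect <- data.frame(truth = rep(c("sit", "walk"), 50),
                        pred = rep(c("sit", "walk"), 50))
  cs <- confusion(perfect)
  expect_true(all(cs$sensitivity == 100 & cs$specificity == 100))

  inverted <- data.frame(truth = rep(c("sit", "walk"), 50),
                         pred = rep(c("walk", "sit"), 50))
  cs <- confusion(inverted)
  expect_true(all(cs$sensitivity == 0 & cs$specificity == 0))

  # every one-vs-rest partition exhausts the paired seconds
  set.seed(5)
  rnd <- data.frame(truth = sample(c("sit", "walk", "run"), 200, TRUE),
                    pred = sample(c("sit", "walk", "run"), 200, TRUE))
  cs <- confusion(rnd)
  expect_true(all(cs$tp + cs$fn + cs$tn + cs$fp == 200))

  # undefined predictions are negatives everywhere: they never appear as
  # an activity row and only cost sensitivity
  und <- data.frame(truth = rep("walk", 10),
                    pred = c(rep("walk", 8), "undefined", "undefined"))
  cs <- confusion(und)
  expect_equal(cs$activity, "walk")
  expect_equal(cs$sensitivity, 80.0)
})

test_that("composition tallies predicted labels within an activity", {
  pred <- label_series(c(rep("walk", 50), rep("run", 30), rep("stand", 20)),
                       t0 = 0.5)
  log <- activity_log("basketball", 0, 100)
  comp <- composition(pred, log, "basketball")
  expect_equal(comp$percent[comp$label == "walk"], 50.0)
  expect_equal(sum(comp$percent), 100.0, tolerance = 0.11)
  expect_error(composition(pred, log, "swing"), "not present")

  solo <- label_series(rep("sit", 30), t0 = 0.5)
  comp <- composition(solo, activity_log("rest", 0, 30), "rest")
  expect_equal(comp, data.frame(label = "sit", percent = 100))

  # brute-force counting oracle on a shuffled stream
  set.seed(7)
  labs <- sample(c("walk", "run", "bike"), 90, TRUE)
  p2 <- label_series(labs, t0 = 0.5)
  comp <- composition(p2, activity_log("playground", 0, 90), "playground")
  for (i in seq_len(nrow(comp))) {
    expect_equal(comp$percent[i],
                 round(100 * sum(labs == comp$label[i]) / 90, 1))
  }
})

test_that("pooled densities locate the separating crossing", {
  set.seed(13)
  f <- data.frame(sd_long = c(rnorm(300, 0.05, 0.01), rnorm(300, 0.5, 0.1)),
                  class = rep(c("stationary", "dynamic"), each = 300))
  dp <- pooled_density(f, "sd_long",
                       list(still = "stationary", moving = "dynamic"))
  expect_gte(length(dp$crossings), 1)
  expect_true(all(dp$crossings > 0.05 & dp$crossings < 0.5))

  # identical pooled samples: the ordering never flips
  same <- data.frame(sd_long = rep(rnorm(100, 0.3, 0.05), 2),
                     class = rep(c("a", "b"), each = 100))
  expect_length(pooled_density(same, "sd_long",
                               list(a = "a", b = "b"))$crossings, 0)

  degen <- data.frame(sd_long = c(rep(0.2, 100), rnorm(100, 0.5, 0.1)),
                      class = rep(c("a", "b"), each = 100))
  expect_error(pooled_density(degen, "sd_long", list(a = "a", b = "b")),
               "zero-variance")
  tiny <- data.frame(sd_long = rnorm(40), class = rep(c("a", "b"), 20))
  expect_error(pooled_density(tiny, "sd_long", list(a = "a", b = "b")),
               ">= 30")
})

test_that("protocol-generated features place angle crossings near the presets", {
  out <- gen_protocol(table_protocol(duration_s = 60, seed = 5), fs = 30)
  feats <- compute_features(out$recording)
  sec <- feats$t
  cls <- rep(NA_character_, nrow(feats))
  for (i in seq_len(nrow(out$log))) {
    inside <- sec >= out$log$start[i] + 2 & sec < out$log$end[i] - 2
    cls[inside] <- out$log$label[i]
  }
  keep <- !is.na(cls)
  f <- feats[keep, ]; f$class <- cls[keep]

  th <- thresholds("child")
  dp <- pooled_density(f, "theta_deg",
                       list(locomotion = c("walk", "run"), biking = "bike"))
  expect_true(any(abs(dp$crossings - th$theta_bike) / th$theta_bike < 0.2))
  dp <- pooled_density(f, "inc_deg",
                       list(sitting = "sit", standing = "stand"))
  expect_true(any(abs(dp$crossings - th$inc_sit) / th$inc_sit < 0.2))
})

test_that("subject splitting is stratified, deterministic and robust", {
  subjects <- data.frame(id = 1:12,
                         group = rep(c("preschool", "child", "adolescent"),
                                     each = 4))
  sp <- split_subjects(subjects, seed = 42)
  expect_equal(unname(table(sp$development$group)[c("adolescent", "child",
                                                    "preschool")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(nrow(sp$validation), 6)
  expect_identical(split_subjects(subjects, 42), sp)

  odd <- data.frame(id = 1:5, group = rep("child", 5))
  so <- split_subjects(odd, 1)
  expect_equal(nrow(so$development), 3)   # odd count favours development
  expect_equal(nrow(so$validation), 2)
  expect_error(split_subjects(data.frame(id = integer(),
                                         group = character()), 1),
               "at least one")
})
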