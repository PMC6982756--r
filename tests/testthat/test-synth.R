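test_that("default activity models encode the intended postures and cadences", {
  models <- defaultActivityModels()
  expect_setequal(names(models), activityLabels())
  expect_equal(models$resting$oscAmp, c(0, 0, 0))
  # at least two distinct postures: upright, prone and supine
  gravs <- unique(lapply(models, `[[`, "gravity"))
  expect_gte(length(gravs), 3L)
})

test_that("accelerometer streams have the prescribed length and moments", {
  models <- defaultActivityModels()
  expect_identical(nrow(generateAccelStream(models$jogging, 30, seed = 1)), 600L)

  # degenerate stream: no noise, no oscillation, pure gravity
  still <- activityModel("resting", c(0, 1, 0), c(0, 0, 0), c(0, 0, 0),
                         noiseSd = 0, hrTarget = 75)
  st <- generateAccelStream(still, 2, seed = 1)
  expect_true(all(st[, "ax"] == 0 & st[, "ay"] == 1 & st[, "az"] == 0))

  # determinism per seed
  expect_identical(generateAccelStream(models$jogging, 10, seed = 4),
                   generateAccelStream(models$jogging, 10, seed = 4))
  expect_false(identical(generateAccelStream(models$jogging, 10, seed = 4),
                         generateAccelStream(models$jogging, 10, seed = 5)))

  # CLT bound: 60 s sample mean within 3 sd/sqrt(n) of the gravity
  # projection (jogging's 2.5 Hz makes 150 whole cycles in 60 s)
  jog <- generateAccelStream(models$jogging, 60, seed = 6)
  n <- nrow(jog)
  for (a in 1:3)
    expect_lte(abs(mean(jog[, a]) - models$jogging$gravity[a]),
               3 * models$jogging$noiseSd / sqrt(n) + 1e-9)

  # parameter recovery on a noise-free jogging stream: windowed std of the
  # vertical axis is amp/sqrt(2) (RMS of a sinusoid), windowed mean is the
  # gravity projection
  pure <- activityModel("jogging", c(0, 1, 0), c(2.5, 2.5, 2.5),
                        c(0, 0.8, 0), noiseSd = 0, hrTarget = 150)
  feats <- do.call(rbind, lapply(segmentWindows(
    generateAccelStream(pure, 30, seed = 7)), computeFeatureVector))
  expect_equal(mean(feats[, "std_y"]), 0.8 / sqrt(2), tolerance = 0.05)
  # with whole cycles per window (2 Hz at 20 Hz sampling) recovery is exact
  pure2 <- activityModel("jogging", c(0, 1, 0), c(2, 2, 2),
                         c(0, 0.8, 0), noiseSd = 0, hrTarget = 150)
  feats2 <- do.call(rbind, lapply(segmentWindows(
    generateAccelStream(pure2, 30, seed = 7)), computeFeatureVector))
  expect_equal(max(abs(feats2[, "mean_y"] - 1)), 0, tolerance = 1e-6)
  expect_equal(mean(feats2[, "std_y"]), 0.8 / sqrt(2), tolerance = 1e-6)

  # jogging shakes the vertical axis >= 5x harder than resting
  restStd <- mean(do.call(rbind, lapply(segmentWindows(
    generateAccelStream(models$resting, 30, seed = 7)),
    computeFeatureVector))[, "std_y"])
  expect_gte(mean(feats[, "std_y"]) / restStd, 5)
})

test_that("activity clusters are well separated in feature space", {
  models <- defaultActivityModels()
  feats <- lapply(models, function(m) {
    w <- segmentWindows(generateAccelStream(m, 60, seed = 30))
    do.call(rbind, lapply(w, computeFeatureVector))[, prunedFeatureSet()]
  })
  acts <- names(models)
  for (i in seq_along(acts)[-length(acts)]) for (j in (i + 1):length(acts)) {
    mi <- colMeans(feats[[i]]); mj <- colMeans(feats[[j]])
    si <- apply(feats[[i]], 2, sd); sj <- apply(feats[[j]], 2, sd)
    sep <- abs(mi - mj) / pmax(si, sj, 1e-12)
    expect_gte(max(sep), 5)
  }
})

test_that("HR streams relax towards the activity target", {
  models <- defaultActivityModels()
  script <- sessionScript(activities = "resting", durations = 60L,
                          hrRest = models$resting$hrTarget)
  # fixed point: start at target with zero noise -> constant series
  hr <- generateHRStream(script, models, seed = 1, noiseSd = 0)
  expect_equal(hr, rep(models$resting$hrTarget, 60))

  # geometric decay: after >= 5 tau the gap to target is <= 1% of the start
  jscript <- sessionScript(activities = "jogging", durations = 120L, hrRest = 70)
  hj <- generateHRStream(jscript, models, seed = 1, noiseSd = 0)
  gap0 <- models$jogging$hrTarget - 70
  after <- 5 * models$jogging$hrTau
  expect_lte(abs(models$jogging$hrTarget - hj[after]), 0.01 * gap0 + 1e-9)

  expect_identical(length(generateHRStream(sessionScript(), models, seed = 2)),
                   240L)
  expect_identical(generateHRStream(sessionScript(), models, seed = 2),
                   generateHRStream(sessionScript(), models, seed = 2))
})

test_that("generated sessions follow the script exactly", {
  script <- sessionScript()   # the 8 x 30 s test routine
  s <- generateSession(script, seed = 17)
  expect_identical(nRecords(s), 240L)
  expect_equal(diff(recordTimestamps(s)), rep(1000, 239))
  # labels appear in script order with the scripted run lengths
  r <- rle(recordLabels(s))
  expect_identical(r$values, script$activities)
  expect_identical(r$lengths, script$durations)
  expect_identical(recordLabels(s)[1], "push-ups")
  # determinism of the full session
  s2 <- generateSession(script, seed = 17)
  expect_identical(s@ax, s2@ax)
  expect_identical(recordHR(s), recordHR(s2))
})

test_that("high-HR activities score harder workloads than low-HR ones", {
  models <- defaultActivityModels()
  mk <- function(act) {
    sc <- sessionScript(activities = act, durations = 120L, age = 27, hrRest = 70)
    s <- generateSession(sc, models, seed = 33)
    scoreSession(s)
  }
  hi <- mk("jogging")     # target 150 bpm
  lo <- mk("crunches")    # target 100 bpm
  tau <- models$jogging$hrTau
  keep <- seq_len(120) > 3 * tau
  lv <- workloadCategories()
  hardnessHi <- match(hi$category[keep], lv)
  hardnessLo <- match(lo$category[keep], lv)
  expect_gte(mean(hardnessHi > hardnessLo), 0.9)
  expect_gt(match(aggregateActivityWorkload(hi$category[keep]), lv),
            match(aggregateActivityWorkload(lo$category[keep]), lv))
})
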