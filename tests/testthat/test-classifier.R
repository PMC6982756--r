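test_that("the stratified split is disjoint, exhaustive and seeded", {
  set.seed(3)
  fm <- FeatureMatrix(matrix(rnorm(100 * 2), 100, 2,
                             dimnames = list(NULL, c("mean_x", "std_x"))),
                      rep(activityLabels(), each = 20))
  parts <- splitDataset(fm, 0.7, seed = 9)
  nTrain <- nrow(featureValues(parts$train))
  nVal <- nrow(featureValues(parts$validation))
  expect_identical(nTrain, 70L)
  expect_identical(nVal, 30L)
  # per-class counts within one vector of the stratified ideal
  trTab <- table(recordLabels(parts$train))
  expect_true(all(abs(trTab - 14) <= 1))
  # determinism: same seed, same partition
  parts2 <- splitDataset(fm, 0.7, seed = 9)
  expect_identical(featureValues(parts$train), featureValues(parts2$train))
  # a class with < 2 members is refused by name
  bad <- FeatureMatrix(featureValues(fm)[1:21, ],
                       c(rep("resting", 20), "jogging"))
  expect_error(splitDataset(bad, 0.7, 1), "jogging")
})

test_that("training is deterministic and sane on degenerate sets", {
  fm <- FeatureMatrix(matrix(rnorm(40), 20, 2,
                             dimnames = list(NULL, c("mean_x", "std_x"))),
                      rep("squatting", 20))
  m <- trainModel(fm, "random_forest", 5, seed = 1)
  probe <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("mean_x", "std_x")))
  expect_true(all(predictActivities(m, probe) == "squatting"))
  expect_error(trainModel(FeatureMatrix(
    matrix(numeric(), 0, 1, dimnames = list(NULL, "mean_x")), character())),
    "empty")

  fm2 <- makeBenchmarkCorpus(4, nSessions = 1L)
  m1 <- trainModel(fm2, "random_forest", 24, seed = 7)
  m2 <- trainModel(fm2, "random_forest", 24, seed = 7)
  probe <- featureValues(makeBenchmarkCorpus(5, nSessions = 1L))
  expect_identical(predictActivities(m1, probe), predictActivities(m2, probe))
})

test_that("well-separated clusters are classified perfectly by both backends", {
  # five clusters spaced >= 10 within-cluster standard deviations apart
  set.seed(10)
  centers <- seq(0, 80, by = 20)   # sd = 1 -> 20 sd separation
  lab <- rep(activityLabels(), each = 30)
  feat <- cbind(mean_x = rnorm(150, rep(centers, each = 30), 1),
                std_x = rnorm(150, 0, 1))
  fm <- FeatureMatrix(feat, lab)
  parts <- splitDataset(fm, 0.7, seed = 2)
  # the nearest-centroid oracle confirms separability
  oracle <- nearestCentroidPredict(featureValues(parts$train),
                                   recordLabels(parts$train),
                                   featureValues(parts$validation))
  expect_identical(oracle, recordLabels(parts$validation))
  for (alg in c("random_forest", "knn")) {
    m <- trainModel(parts$train, alg, if (alg == "knn") 5 else 24, seed = 2)
    expect_equal(overallAccuracy(evaluateModel(m, parts$validation)), 1.0)
  }
})

test_that("evaluation counts match brute-force tallies", {
  cls <- c("jogging", "resting")
  # hand-built outcome: 10 items, 7 correct
  truth <- c(rep("jogging", 5), rep("resting", 5))
  pred <- c("jogging", "jogging", "resting", "jogging", "resting",
            "resting", "resting", "resting", "jogging", "resting")
  rep1 <- harload:::buildReport(truth, pred, cls)
  expect_equal(overallAccuracy(rep1), 0.7)
  expect_equal(confusionMatrix(rep1)["jogging", "jogging"], 3 / 5)
  expect_equal(confusionMatrix(rep1)["resting", "jogging"], 1 / 5)
  expect_equal(unname(rowSums(confusionMatrix(rep1))), c(1, 1))

  # identity predictions -> identity confusion; all-wrong -> zero diagonal
  repId <- harload:::buildReport(truth, truth, cls)
  expect_equal(confusionMatrix(repId), diag(2), ignore_attr = TRUE)
  expect_equal(overallAccuracy(repId), 1.0)
  repWrong <- harload:::buildReport(truth, rev(truth), cls)
  expect_equal(unname(diag(confusionMatrix(repWrong))), c(0, 0))
  expect_equal(overallAccuracy(repWrong), 0.0)

  # labels outside the model's class list are refused
  fm <- makeBenchmarkCorpus(6, nSessions = 1L)
  m <- trainModel(fm, "random_forest", 8, seed = 1)
  alien <- FeatureMatrix(featureValues(fm)[1:4, ],
                         rep("resting", 4))
  alien@labels[1] <- "jogging"   # fine; now poison the class list instead
  m@classes <- setdiff(m@classes, "resting")
  expect_error(evaluateModel(m, alien), "outside the model's class list")
})

test_that("the size sweep is one fit per size and stabilises with trees", {
  fm <- makeBenchmarkCorpus(8, nSessions = 1L)
  parts <- splitDataset(fm, 0.7, seed = 8)
  curve <- sweepSize(parts$train, parts$validation, "random_forest",
                     c(2L, 10L, 20L, 24L), seed = 8)
  expect_identical(nrow(curve), 4L)
  expect_identical(curve$size, c(2L, 10L, 20L, 24L))
  # single-value sweep equals a direct train + evaluate
  one <- sweepSize(parts$train, parts$validation, "random_forest", 24L, seed = 8)
  direct <- overallAccuracy(evaluateModel(
    trainModel(parts$train, "random_forest", 24L,
               seed = harload:::deriveSeed(8, "sweep24")),
    parts$validation))
  expect_equal(one$accuracy, direct)
  # accuracy with >= 20 trees never falls below the 2-tree accuracy by > 0.02
  expect_true(all(curve$accuracy[curve$size >= 20] >=
                    curve$accuracy[curve$size == 2] - 0.02))
  # all sweep accuracies stay near the nearest-centroid oracle
  oracle <- mean(nearestCentroidPredict(featureValues(parts$train),
                                        recordLabels(parts$train),
                                        featureValues(parts$validation)) ==
                   recordLabels(parts$validation))
  expect_true(all(curve$accuracy >= oracle - 0.05))
  expect_error(sweepSize(parts$train, parts$validation, "random_forest",
                         integer(0)), "non-empty")
})

test_that("Gini importance is normalised and finds the informative feature", {
  set.seed(20)
  n <- 400
  f <- rnorm(n)
  noise <- matrix(rnorm(n * 3), n, 3)
  feat <- cbind(mean_x = noise[, 1], std_x = f, var_x = noise[, 2],
                mad_x = noise[, 3], dmean_xy = rep(0, n))  # constant feature
  lab <- ifelse(f > 0, "jogging", "resting")
  fm <- FeatureMatrix(feat, lab)
  m <- trainModel(fm, "random_forest", 30, seed = 3)
  imp <- rankImportance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "std_x")
  expect_lte(imp[["dmean_xy"]], 0.01)
  # kNN models have no impurity-based importance
  mk <- trainModel(fm, "knn", 5, seed = 3)
  expect_error(rankImportance(mk), "random forest")
})

test_that("pruned spec selection drops the lowest-importance features", {
  r <- c(0.30, 0.25, 0.15, 0.10, 0.08, 0.06, 0.04, 0.02)
  names(r) <- fullFeatureSet()[1:8]
  spec <- selectPrunedSpec(r, 3)
  dropped <- names(sort(r))[1:3]
  expect_identical(spec, setdiff(names(r), dropped))
  expect_identical(selectPrunedSpec(r, 0), names(r))
  expect_error(selectPrunedSpec(r, 8), "smaller")
  # 15 features minus 4 leaves the 11-feature operating set
  r15 <- rep(1 / 15, 15); names(r15) <- fullFeatureSet()
  expect_length(selectPrunedSpec(r15, 4), 11L)
})

test_that("the portable description replays the live forest exactly", {
  fm <- makeBenchmarkCorpus(12, nSessions = 1L)
  parts <- splitDataset(fm, 0.7, seed = 12)
  m <- trainModel(parts$train, "random_forest", 24, seed = 12)
  path <- tempfile(fileext = ".json")
  exportModel(m, path)
  desc <- readModelDescription(path)
  expect_identical(length(desc$trees), 24L)
  expect_identical(unlist(desc$feature_names), prunedFeatureSet())

  probe <- makeBenchmarkCorpus(13, nSessions = 1L)
  expect_identical(replayModel(path, probe), predictActivities(m, probe))

  # a single-stump forest contains exactly one split node
  set.seed(1)
  twocl <- FeatureMatrix(cbind(mean_x = c(rnorm(30, -4), rnorm(30, 4))),
                         rep(c("resting", "jogging"), each = 30))
  stump <- trainModel(twocl, "random_forest", 1, seed = 1)
  expect_identical(countSplitNodes(exportModel(stump)), 1L)

  expect_error(exportModel(trainModel(twocl, "knn", 5, seed = 1)),
               "random-forest")
})
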