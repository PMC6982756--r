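#' Stratified train/validation split
#'
#' Randomly partitions labelled feature vectors into disjoint, exhaustive
#' train and validation subsets, stratified by activity so every class is
#' represented on both sides. The shuffle is driven entirely by \code{seed}.
#'
#' @param x a labelled \code{\linkS4class{FeatureMatrix}}.
#' @param trainFraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#'
#' @return List with elements \code{train} and \code{validation}, both
#'   \code{FeatureMatrix} objects.
#' @export
splitDataset <- function(x, trainFraction = 0.7, seed = 1L) {
  stopifnot(is(x, "FeatureMatrix"), trainFraction > 0, trainFraction < 1)
  lab <- x@labels
  if (anyNA(lab)) stop("all vectors must be labelled")
  counts <- table(lab)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("class with fewer than 2 members: ", paste(small, collapse = ", "))
  set.seed(deriveSeed(seed, "split"))
  trainIdx <- integer(0)
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    idx <- sample(idx)
    nTrain <- max(1L, min(length(idx) - 1L, round(trainFraction * length(idx))))
    trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
  }
  trainIdx <- sort(trainIdx)
  valIdx <- setdiff(seq_along(lab), trainIdx)
  list(
    train = FeatureMatrix(x@features[trainIdx, , drop = FALSE], lab[trainIdx]),
    validation = FeatureMatrix(x@features[valIdx, , drop = FALSE], lab[valIdx])
  )
}

#' Train an activity classifier
#'
#' Fits a random forest (the deployed choice) or a k-nearest-neighbour
#' baseline on labelled feature vectors. Training is deterministic given
#' \code{seed}. Hyperparameters beyond \code{sizeParam} are left at the
#' backend's impurity-based defaults.
#'
#' @param train labelled \code{\linkS4class{FeatureMatrix}}.
#' @param algorithm \code{"random_forest"} or \code{"knn"}.
#' @param sizeParam tree count (forest) or neighbour count (kNN); the
#'   deployed defaults are 24 trees and 5 neighbours.
#' @param seed integer seed.
#'
#' @return A \code{\linkS4class{HARModel}}.
#' @export
trainModel <- function(train, algorithm = c("random_forest", "knn"),
                       sizeParam = 24L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(is(train, "FeatureMatrix"))
  if (nrow(train@features) == 0L) stop("empty training set")
  if (anyNA(train@labels)) stop("training vectors must be labelled")
  sizeParam <- as.integer(sizeParam)
  if (sizeParam < 1L || sizeParam > 1000L)
    stop("sizeParam must lie in 1..1000")
  classes <- sort(unique(train@labels))
  y <- factor(train@labels, levels = classes)
  fit <- if (length(classes) == 1L) {
    # degenerate but legal: a single-class set yields a constant classifier
    list(constant = classes)
  } else if (algorithm == "random_forest") {
    set.seed(deriveSeed(seed, "train_rf"))
    randomForest::randomForest(x = train@features, y = y, ntree = sizeParam)
  } else {
    # kNN is a lazy learner: keep the training set and classify at query time
    list(x = train@features, y = y)
  }
  new("HARModel", algorithm = algorithm, sizeParam = sizeParam,
      featureNames = colnames(train@features), classes = classes,
      fit = fit, seed = as.integer(seed))
}

#' Predict activity labels
#'
#' Classifies feature vectors with a trained model. Forest predictions are
#' taken as the majority of per-tree votes with ties broken by canonical
#' (alphabetical) activity order, so predictions are deterministic and match
#' the portable model description replayed by \code{\link{replayModel}}.
#'
#' @param model a \code{\linkS4class{HARModel}}.
#' @param x a \code{FeatureMatrix} or numeric matrix whose columns cover the
#'   model's feature set.
#'
#' @return Character vector of predicted activity labels.
#' @export
predictActivities <- function(model, x) {
  stopifnot(is(model, "HARModel"))
  feat <- if (is(x, "FeatureMatrix")) x@features else as.matrix(x)
  miss <- setdiff(model@featureNames, colnames(feat))
  if (length(miss))
    stop("feature(s) missing from input: ", paste(miss, collapse = ", "))
  feat <- feat[, model@featureNames, drop = FALSE]
  if (is.list(model@fit) && !is.null(model@fit$constant))
    return(rep(model@fit$constant, nrow(feat)))
  if (model@algorithm == "random_forest") {
    votes <- stats::predict(model@fit, feat, type = "vote", norm.votes = FALSE)
    votes <- votes[, model@classes, drop = FALSE]
    model@classes[apply(votes, 1L, which.max)]
  } else {
    set.seed(deriveSeed(model@seed, "knn_predict"))
    as.character(class::knn(model@fit$x, feat, model@fit$y,
                            k = model@sizeParam))
  }
}

#' Evaluate a classifier on labelled vectors
#'
#' Builds the per-true-class confusion matrix by exact counting followed by
#' row normalisation, plus overall and per-class accuracies.
#'
#' @param model a \code{\linkS4class{HARModel}}.
#' @param x labelled \code{\linkS4class{FeatureMatrix}}.
#'
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @export
evaluateModel <- function(model, x) {
  stopifnot(is(model, "HARModel"), is(x, "FeatureMatrix"))
  if (nrow(x@features) == 0L) stop("no vectors to evaluate")
  if (anyNA(x@labels)) stop("vectors must be labelled")
  bad <- setdiff(unique(x@labels), model@classes)
  if (length(bad))
    stop("label(s) outside the model's class list: ", paste(bad, collapse = ", "))
  pred <- predictActivities(model, x)
  buildReport(truth = x@labels, pred = pred, classes = model@classes)
}

# Shared by evaluateModel and the CLI: confusion from explicit tallies.
buildReport <- function(truth, pred, classes) {
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth))
    counts[truth[i], pred[i]] <- counts[truth[i], pred[i]] + 1L
  support <- rowSums(counts)
  conf <- counts / ifelse(support == 0L, 1L, support)
  perClass <- diag(conf)
  names(perClass) <- classes
  storage.mode(support) <- "integer"
  new("EvaluationReport", confusion = conf, counts = counts,
      overallAccuracy = sum(diag(counts)) / length(truth),
      perClassAccuracy = perClass, support = support)
}

#' Sweep the model size parameter
#'
#' Trains one model per size value on a fixed train/validation split and
#' records held-out overall accuracy, reproducing the tree-count (or
#' neighbour-count) tuning curve. Each size gets its own deterministically
#' derived seed.
#'
#' @param train,validation labelled \code{FeatureMatrix} objects from one
#'   split.
#' @param algorithm \code{"random_forest"} or \code{"knn"}.
#' @param sizeRange ascending integer vector of size values (e.g.
#'   \code{2:100} trees).
#' @param seed integer seed.
#'
#' @return \code{data.frame} with columns \code{size} and \code{accuracy}.
#' @export
sweepSize <- function(train, validation, algorithm = "random_forest",
                      sizeRange = 2:100, seed = 1L) {
  if (!length(sizeRange)) stop("sizeRange must be non-empty")
  if (is.unsorted(sizeRange, strictly = TRUE)) stop("sizeRange must be ascending")
  acc <- vapply(sizeRange, function(sz) {
    m <- trainModel(train, algorithm, sz, seed = deriveSeed(seed, paste0("sweep", sz)))
    overallAccuracy(evaluateModel(m, validation))
  }, numeric(1))
  data.frame(size = as.integer(sizeRange), accuracy = acc)
}

#' Gini feature importance of a trained forest
#'
#' Normalised mean-decrease-in-impurity (Gini) importance per feature,
#' summing to 1, in the model's canonical feature order.
#'
#' @param model a random-forest \code{\linkS4class{HARModel}}.
#'
#' @return Named numeric vector of importances (non-negative, sum 1).
#' @export
rankImportance <- function(model) {
  stopifnot(is(model, "HARModel"))
  if (model@algorithm != "random_forest")
    stop("feature importance is only defined for random forests")
  imp <- model@fit$importance[, "MeanDecreaseGini"]
  imp <- imp[model@featureNames]
  tot <- sum(imp)
  if (tot <= 0) stop("degenerate forest: zero total impurity decrease")
  imp / tot
}

#' Select a pruned feature set from an importance ranking
#'
#' Drops the \code{dropCount} lowest-importance features; ties are broken by
#' canonical feature order (earlier features dropped first among equals).
#' Retained features keep their canonical order.
#'
#' @param ranking named importance vector from \code{\link{rankImportance}}.
#' @param dropCount how many features to drop (the deployed pipeline drops 4,
#'   going from 15 to 11 features).
#'
#' @return Character vector naming the retained features, in canonical order.
#' @export
selectPrunedSpec <- function(ranking, dropCount) {
  dropCount <- as.integer(dropCount)
  if (dropCount < 0L) stop("dropCount must be non-negative")
  if (dropCount >= length(ranking))
    stop("dropCount must be smaller than the number of features")
  ord <- order(ranking, seq_along(ranking))
  dropped <- names(ranking)[ord[seq_len(dropCount)]]
  names(ranking)[!names(ranking) %in% dropped]
}
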