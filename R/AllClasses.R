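#' @import methods
NULL

#' Canonical activity labels
#'
#' The closed set of activities the pipeline recognises, in canonical
#' (alphabetical) order. The order is also the tie-break order for
#' classifier votes.
#'
#' @return Character vector of the five activity names.
#' @export
activityLabels <- function() {
  c("crunches", "jogging", "push-ups", "resting", "squatting")
}

#' Workload categories in increasing order of hardness
#'
#' The eight qualitative workload categories of Frimat's criterion, ordered
#' from lightest to hardest. Category comparisons (e.g. tie-breaking in
#' per-activity aggregation) use this ordering.
#'
#' @return Character vector of length 8, lightest first.
#' @export
workloadCategories <- function() {
  c("Minimum workload", "Very light", "Light", "Bearable",
    "Distressing", "Hard", "Very hard", "Extremely hard")
}

## Sensor full scale (ADXL335-class part): +/- 2 g
ACCEL_FULL_SCALE <- 2.0
SAMPLES_PER_SECOND <- 20L

#' SensorSession: a per-second wearable sensor stream
#'
#' Container for one recording session: per-second records each holding 20
#' triaxial accelerometer samples (units of g, 20 Hz) and a one-second mean
#' heart rate (bpm), plus subject metadata used for workload scoring.
#'
#' @slot userId single character subject identifier.
#' @slot age subject age in years (may be \code{NA} when only activity
#'   recognition is performed).
#' @slot hrRest subject resting heart rate in bpm (may be \code{NA} before
#'   estimation).
#' @slot timestamp numeric vector of record timestamps, integer-valued epoch
#'   milliseconds, strictly increasing.
#' @slot label character vector of activity labels, one per record, drawn
#'   from \code{\link{activityLabels}}.
#' @slot hr numeric vector of per-second mean heart rates in bpm; \code{NA}
#'   allowed for streams used for activity recognition alone.
#' @slot ax,ay,az numeric matrices (records x 20) of per-axis accelerometer
#'   samples in g; column k holds the sample at offset (k-1) * 50 ms.
#'
#' @export
setClass("SensorSession",
  representation(
    userId = "character",
    age = "numeric",
    hrRest = "numeric",
    timestamp = "numeric",
    label = "character",
    hr = "numeric",
    ax = "matrix",
    ay = "matrix",
    az = "matrix"
  )
)

setValidity("SensorSession", function(object) {
  msg <- character()
  n <- length(object@timestamp)
  if (length(object@userId) != 1L) msg <- c(msg, "userId must be a single string")
  if (length(object@age) != 1L || length(object@hrRest) != 1L)
    msg <- c(msg, "age and hrRest must be length-1")
  if (!is.na(object@age) && (object@age < 1 || object@age > 119))
    msg <- c(msg, "age must lie in 1..119 years")
  if (length(object@label) != n || length(object@hr) != n)
    msg <- c(msg, "label and hr must have one entry per record")
  for (s in c("ax", "ay", "az")) {
    m <- slot(object, s)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != SAMPLES_PER_SECOND)
      msg <- c(msg, sprintf("%s must be a numeric records x %d matrix", s, SAMPLES_PER_SECOND))
    else if (any(abs(m) > ACCEL_FULL_SCALE + 1e-12))
      msg <- c(msg, sprintf("%s exceeds the +/-%g g sensor full scale", s, ACCEL_FULL_SCALE))
  }
  if (n > 1 && any(diff(object@timestamp) <= 0))
    msg <- c(msg, "record timestamps must be strictly increasing")
  bad <- setdiff(unique(object@label), activityLabels())
  if (length(bad))
    msg <- c(msg, paste0("unknown activity label(s): ", paste(bad, collapse = ", ")))
  hrv <- object@hr[!is.na(object@hr)]
  if (length(hrv) && (any(hrv <= 20) || any(hrv >= 250)))
    msg <- c(msg, "mean_hr values must lie in (20, 250) bpm")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorSession
#'
#' @param userId single character subject id.
#' @param timestamp numeric vector of epoch milliseconds, strictly increasing.
#' @param label character vector of activity labels.
#' @param hr numeric vector of per-second mean HR (bpm), \code{NA} permitted.
#' @param ax,ay,az numeric records x 20 matrices of accelerometer samples (g).
#' @param age subject age in years, or \code{NA}.
#' @param hrRest subject resting HR in bpm, or \code{NA}.
#'
#' @return A validated \code{\linkS4class{SensorSession}}.
#' @export
SensorSession <- function(userId, timestamp, label, hr, ax, ay, az,
                          age = NA_real_, hrRest = NA_real_) {
  new("SensorSession",
      userId = as.character(userId),
      age = as.numeric(age), hrRest = as.numeric(hrRest),
      timestamp = as.numeric(timestamp), label = as.character(label),
      hr = as.numeric(hr),
      ax = as.matrix(ax), ay = as.matrix(ay), az = as.matrix(az))
}

#' FeatureMatrix: labelled per-window feature vectors
#'
#' One row per one-second window; columns are the statistical features in
#' canonical order (see \code{\link{fullFeatureSet}}). Labels may be
#' \code{NA} for unlabelled streams.
#'
#' @slot features numeric matrix, windows x features, with feature names as
#'   column names.
#' @slot labels character vector of activity labels, one per row.
#' @export
setClass("FeatureMatrix",
  representation(features = "matrix", labels = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "one label per feature row required")
  if (is.null(colnames(object@features)))
    msg <- c(msg, "feature columns must be named")
  known <- object@labels[!is.na(object@labels)]
  bad <- setdiff(unique(known), activityLabels())
  if (length(bad))
    msg <- c(msg, paste0("unknown activity label(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureMatrix-class
#' @param features numeric windows x features matrix with column names.
#' @param labels character labels, recycled \code{NA} if missing.
#' @export
FeatureMatrix <- function(features, labels = rep(NA_character_, nrow(features))) {
  new("FeatureMatrix", features = features, labels = as.character(labels))
}

#' HARModel: a trained activity classifier
#'
#' Wraps either a random forest or a k-nearest-neighbour classifier together
#' with the feature set it was trained on, its ordered class list and the
#' seed that reproduces it.
#'
#' @slot algorithm \code{"random_forest"} or \code{"knn"}.
#' @slot sizeParam tree count (random forest) or neighbour count (kNN).
#' @slot featureNames ordered character vector of the features in effect.
#' @slot classes ordered (alphabetical) activity names seen in training.
#' @slot fit the fitted backend object.
#' @slot seed integer seed used for training.
#' @export
setClass("HARModel",
  representation(algorithm = "character", sizeParam = "integer",
                 featureNames = "character", classes = "character",
                 fit = "ANY", seed = "integer"))

setValidity("HARModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("random_forest", "knn"))
    msg <- c(msg, "algorithm must be random_forest or knn")
  if (length(object@sizeParam) != 1L || object@sizeParam < 1L)
    msg <- c(msg, "sizeParam must be a positive integer")
  if (!length(object@classes)) msg <- c(msg, "classes must be non-empty")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: confusion matrix and accuracies
#'
#' @slot confusion per-true-class row-normalised confusion matrix; rows with
#'   zero support are all zero (see \code{support}).
#' @slot counts raw confusion counts.
#' @slot overallAccuracy fraction of correct predictions in [0, 1].
#' @slot perClassAccuracy named per-activity accuracy (diagonal of
#'   \code{confusion}).
#' @slot support named integer count of true instances per class.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", counts = "matrix",
                 overallAccuracy = "numeric", perClassAccuracy = "numeric",
                 support = "integer"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  rs <- rowSums(object@confusion)
  ok <- abs(rs - 1) <= 1e-9 | (object@support == 0L & rs == 0)
  if (!all(ok)) msg <- c(msg, "confusion rows must sum to 1 (or 0 for empty classes)")
  if (object@overallAccuracy < 0 || object@overallAccuracy > 1)
    msg <- c(msg, "overallAccuracy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CardiacIndicators: the five quantities of Frimat's criterion
#'
#' @slot acc absolute cardiac cost (bpm): activity mean HR minus resting HR.
#' @slot rcc relative cardiac cost as a dimensionless fraction:
#'   \code{acc / (hrMax - hrRest)}.
#' @slot hrMax theoretical maximum HR, \code{220 - age} (bpm).
#' @slot hrMean windowed mean HR (bpm).
#' @slot deltaHR cardiac acceleration, \code{hrMax - hrMean} (bpm).
#' @export
setClass("CardiacIndicators",
  representation(acc = "numeric", rcc = "numeric", hrMax = "numeric",
                 hrMean = "numeric", deltaHR = "numeric"))

setValidity("CardiacIndicators", function(object) {
  msg <- character()
  if (object@hrMax <= 0) msg <- c(msg, "hrMax must be positive")
  if (abs(object@deltaHR - (object@hrMax - object@hrMean)) > 1e-9)
    msg <- c(msg, "deltaHR must equal hrMax - hrMean")
  if (length(msg)) msg else TRUE
})

#' FrimatAssessment: coefficients, score and category for one window
#'
#' @slot indicators the \code{\linkS4class{CardiacIndicators}} assessed.
#' @slot coefficients named integer vector (acc, rcc, hr_max, hr_mean,
#'   delta_hr), each in 1..5.
#' @slot score integer sum of the five coefficients, in 5..25.
#' @slot category qualitative workload category from
#'   \code{\link{workloadCategories}}.
#' @export
setClass("FrimatAssessment",
  representation(indicators = "CardiacIndicators", coefficients = "integer",
                 score = "integer", category = "character"))

setValidity("FrimatAssessment", function(object) {
  msg <- character()
  if (length(object@coefficients) != 5L ||
      any(object@coefficients < 1L | object@coefficients > 5L))
    msg <- c(msg, "exactly five coefficients in 1..5 required")
  if (object@score != sum(object@coefficients))
    msg <- c(msg, "score must equal the sum of the coefficients")
  if (!object@category %in% workloadCategories())
    msg <- c(msg, "unknown workload category")
  if (length(msg)) msg else TRUE
})
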