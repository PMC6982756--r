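#' @name accessors
#' @title Accessors for harload classes
#'
#' @description Small accessor layer so downstream code never touches slots
#' directly.
#'
#' @param x a harload object.
#' @param i record index.
NULL

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setMethod("nRecords", "SensorSession", function(x) length(x@timestamp))

#' @rdname accessors
#' @export
setGeneric("userId", function(x) standardGeneric("userId"))

#' @rdname accessors
#' @export
setMethod("userId", "SensorSession", function(x) x@userId)

#' @rdname accessors
#' @export
setGeneric("subjectAge", function(x) standardGeneric("subjectAge"))

#' @rdname accessors
#' @export
setMethod("subjectAge", "SensorSession", function(x) x@age)

#' @rdname accessors
#' @export
setGeneric("restingHR", function(x) standardGeneric("restingHR"))

#' @rdname accessors
#' @export
setMethod("restingHR", "SensorSession", function(x) x@hrRest)

#' @rdname accessors
#' @export
setGeneric("recordLabels", function(x) standardGeneric("recordLabels"))

#' @rdname accessors
#' @export
setMethod("recordLabels", "SensorSession", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("recordHR", function(x) standardGeneric("recordHR"))

#' @rdname accessors
#' @export
setMethod("recordHR", "SensorSession", function(x) x@hr)

#' @rdname accessors
#' @export
setGeneric("recordTimestamps", function(x) standardGeneric("recordTimestamps"))

#' @rdname accessors
#' @export
setMethod("recordTimestamps", "SensorSession", function(x) x@timestamp)

#' Accelerometer samples of one record
#'
#' @param x a \code{SensorSession}.
#' @param i record index (1-based).
#' @return 20 x 3 numeric matrix with columns \code{ax}, \code{ay}, \code{az}.
#' @export
accelWindow <- function(x, i) {
  stopifnot(is(x, "SensorSession"), i >= 1, i <= nRecords(x))
  cbind(ax = x@ax[i, ], ay = x@ay[i, ], az = x@az[i, ])
}

#' Full accelerometer stream of a session
#'
#' Concatenates all per-record windows in time order.
#'
#' @param x a \code{SensorSession}.
#' @return (20 * records) x 3 numeric matrix with columns ax, ay, az.
#' @export
accelStream <- function(x) {
  stopifnot(is(x, "SensorSession"))
  cbind(ax = as.vector(t(x@ax)), ay = as.vector(t(x@ay)), az = as.vector(t(x@az)))
}

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("recordLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@features))

#' @rdname accessors
#' @export
setMethod("featureNames", "HARModel", function(x) x@featureNames)

#' @rdname accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))

#' @rdname accessors
#' @export
setMethod("modelClasses", "HARModel", function(x) x@classes)

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname accessors
#' @export
setMethod("overallAccuracy", "EvaluationReport", function(x) x@overallAccuracy)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))

#' @rdname accessors
#' @export
setMethod("perClassAccuracy", "EvaluationReport", function(x) x@perClassAccuracy)

#' @rdname accessors
#' @export
setGeneric("classSupport", function(x) standardGeneric("classSupport"))

#' @rdname accessors
#' @export
setMethod("classSupport", "EvaluationReport", function(x) x@support)

#' @rdname accessors
#' @export
setGeneric("frimatCoefficients", function(x) standardGeneric("frimatCoefficients"))

#' @rdname accessors
#' @export
setMethod("frimatCoefficients", "FrimatAssessment", function(x) x@coefficients)

#' @rdname accessors
#' @export
setGeneric("frimatScoreValue", function(x) standardGeneric("frimatScoreValue"))

#' @rdname accessors
#' @export
setMethod("frimatScoreValue", "FrimatAssessment", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("workloadCategory", function(x) standardGeneric("workloadCategory"))

#' @rdname accessors
#' @export
setMethod("workloadCategory", "FrimatAssessment", function(x) x@category)

#' @rdname accessors
#' @export
setGeneric("cardiacIndicators", function(x) standardGeneric("cardiacIndicators"))

#' @rdname accessors
#' @export
setMethod("cardiacIndicators", "FrimatAssessment", function(x) {
  ind <- x@indicators
  c(acc = ind@acc, rcc = ind@rcc, hr_max = ind@hrMax,
    hr_mean = ind@hrMean, delta_hr = ind@deltaHR)
})

setMethod("show", "SensorSession", function(object) {
  cat("SensorSession for user", object@userId, "\n")
  cat(" ", nRecords(object), "one-second records,",
      nRecords(object) * SAMPLES_PER_SECOND, "accelerometer samples\n")
  cat("  activities:", paste(sort(unique(object@label)), collapse = ", "), "\n")
  cat("  age:", object@age, " resting HR:", object@hrRest, "bpm\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@features), "windows x",
      ncol(object@features), "features\n")
  cat("  features:", paste(colnames(object@features), collapse = ", "), "\n")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab))
    cat("  labels:", paste(sort(unique(lab)), collapse = ", "), "\n")
})

setMethod("show", "HARModel", function(object) {
  cat("HARModel:", object@algorithm,
      sprintf("(%s = %d)\n",
              if (object@algorithm == "random_forest") "trees" else "neighbours",
              object@sizeParam))
  cat("  features (", length(object@featureNames), "): ",
      paste(object@featureNames, collapse = ", "), "\n", sep = "")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: overall accuracy %.4f\n", object@overallAccuracy))
  print(round(object@confusion, 3))
})

setMethod("show", "FrimatAssessment", function(object) {
  cat("FrimatAssessment: score", object@score, "->", object@category, "\n")
  print(object@coefficients)
})
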