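# Lower edges of the coefficient bins for each cardiac indicator. The bins
# are half-open, integer-anchored intervals; e.g. for ACC: [10,15) -> 1,
# [15,20) -> 2, [20,25) -> 3, [25,30) -> 4, [30,Inf) -> 5. Values below the
# lowest edge clamp to coefficient 1 (the score floor of 5 requires every
# coefficient >= 1). RCC is binned as a dimensionless fraction.
FRIMAT_BINS <- list(
  acc      = c(10, 15, 20, 25, 30),
  rcc      = c(0.10, 0.15, 0.20, 0.25, 0.30),
  hr_max   = c(110, 120, 130, 140, 150),
  hr_mean  = c(90, 95, 100, 105, 110),
  delta_hr = c(20, 25, 30, 35, 40)
)

#' Estimate resting heart rate from resting-period measurements
#'
#' The resting HR is the statistical mode of the HR values measured during
#' resting periods, after rounding to the nearest integer bpm. Multimodal
#' ties resolve to the smallest modal value, which is conservative: a lower
#' resting HR raises the absolute cardiac cost attributed to activity.
#'
#' @param hrValues numeric vector of positive HR measurements (bpm).
#' @return Single numeric resting HR (integer-valued bpm).
#' @export
estimateRestingHR <- function(hrValues) {
  if (!length(hrValues)) stop("no resting HR values supplied")
  if (any(!is.finite(hrValues)) || any(hrValues <= 0))
    stop("resting HR values must be positive and finite")
  integerMode(hrValues)
}

#' Compute the five cardiac indicators of Frimat's criterion
#'
#' \describe{
#'   \item{ACC}{absolute cardiac cost, activity mean HR minus resting HR.}
#'   \item{RCC}{relative cardiac cost, \code{ACC / (HRmax - HRrest)}, stored
#'     as a dimensionless fraction of the cardiac reserve.}
#'   \item{HRmax}{theoretical maximum HR, \code{220 - age}.}
#'   \item{HRmean}{mean HR within the (one-second) window.}
#'   \item{deltaHR}{cardiac acceleration, \code{HRmax - HRmean}.}
#' }
#'
#' @param hrActivityMean mean HR during the activity (bpm).
#' @param hrRest resting HR (bpm); must be below \code{220 - age}.
#' @param age subject age in whole years, 1..119.
#' @param hrWindowMean mean HR of the scored window (bpm); defaults to
#'   \code{hrActivityMean}.
#'
#' @return A \code{\linkS4class{CardiacIndicators}} object.
#' @export
computeIndicators <- function(hrActivityMean, hrRest, age,
                              hrWindowMean = hrActivityMean) {
  if (is.na(age) || age < 1 || age > 119) stop("age must lie in 1..119 years")
  vals <- c(hrActivityMean, hrRest, hrWindowMean)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("heart rates must be positive and finite")
  hrMax <- 220 - age
  if (hrRest >= hrMax)
    stop("degenerate cardiac reserve: resting HR ", hrRest,
         " is not below HRmax = ", hrMax)
  acc <- hrActivityMean - hrRest
  new("CardiacIndicators",
      acc = acc, rcc = acc / (hrMax - hrRest), hrMax = hrMax,
      hrMean = hrWindowMean, deltaHR = hrMax - hrWindowMean)
}

#' Map a cardiac indicator value to its Frimat coefficient
#'
#' Bins a value into an integer coefficient 1..5 using the half-open,
#' integer-anchored intervals of the published coefficient table. Values
#' below the lowest bin clamp to 1; values at or above the top bin map to 5.
#' RCC must be supplied as a fraction (e.g. 0.22, not 22).
#'
#' @param indicator one of \code{"acc"}, \code{"rcc"}, \code{"hr_max"},
#'   \code{"hr_mean"}, \code{"delta_hr"}.
#' @param value finite indicator value.
#'
#' @return Integer coefficient in 1..5.
#' @export
coefficientFor <- function(indicator, value) {
  if (length(indicator) != 1L || !indicator %in% names(FRIMAT_BINS))
    stop("unknown indicator: ", paste(indicator, collapse = ", "))
  if (length(value) != 1L || !is.finite(value))
    stop("value must be a single finite number")
  max(1L, findInterval(value, FRIMAT_BINS[[indicator]]))
}

#' Frimat score: sum of the five coefficients
#'
#' @param coefficients exactly five integers, each in 1..5 (one per cardiac
#'   indicator).
#' @return Integer score in 5..25.
#' @export
frimatScore <- function(coefficients) {
  if (length(coefficients) != 5L)
    stop("exactly five coefficients are required")
  if (any(is.na(coefficients)) || any(coefficients != round(coefficients)) ||
      any(coefficients < 1 | coefficients > 5))
    stop("each coefficient must be an integer in 1..5")
  as.integer(sum(coefficients))
}

#' Qualitative workload category of a Frimat score
#'
#' Maps an integer score 5..25 to its category: 25 Extremely hard, 24 Very
#' hard, 22-23 Hard, 20-21 Distressing, 18-19 Bearable, 14-17 Light, 11-13
#' Very light, 10 and below Minimum workload. (The published ranking leaves
#' score 11 without a band; it is assigned to Very light, the nearest band
#' above, keeping the category monotone in the score.)
#'
#' @param score integer score in 5..25.
#' @return Category string from \code{\link{workloadCategories}}.
#' @export
rankScore <- function(score) {
  if (length(score) != 1L || is.na(score) || score != round(score) ||
      score < 5 || score > 25)
    stop("score must be an integer in 5..25")
  if (score >= 25) "Extremely hard"
  else if (score == 24) "Very hard"
  else if (score >= 22) "Hard"
  else if (score >= 20) "Distressing"
  else if (score >= 18) "Bearable"
  else if (score >= 14) "Light"
  else if (score >= 11) "Very light"
  else "Minimum workload"
}

#' Assess the workload of one HR window
#'
#' Composes the full per-window pipeline: cardiac indicators from the window
#' mean HR, coefficient lookup for each of the five indicators, score
#' summation and qualitative ranking. The window mean HR plays the role of
#' the activity mean HR, matching the deployed per-second implementation.
#'
#' @param hrWindowMean mean HR of the one-second window (bpm).
#' @param hrRest resting HR (bpm).
#' @param age subject age in years.
#'
#' @return A \code{\linkS4class{FrimatAssessment}}.
#' @export
assessWindow <- function(hrWindowMean, hrRest, age) {
  ind <- computeIndicators(hrWindowMean, hrRest, age, hrWindowMean)
  coefs <- c(
    acc      = coefficientFor("acc", ind@acc),
    rcc      = coefficientFor("rcc", ind@rcc),
    hr_max   = coefficientFor("hr_max", ind@hrMax),
    hr_mean  = coefficientFor("hr_mean", ind@hrMean),
    delta_hr = coefficientFor("delta_hr", ind@deltaHR)
  )
  score <- frimatScore(coefs)
  new("FrimatAssessment", indicators = ind, coefficients = coefs,
      score = score, category = rankScore(score))
}

#' Aggregate per-window workloads into one per-activity category
#'
#' The estimated workload of an activity segment is the statistical mode of
#' its per-window categories. Ties resolve to the harder category
#' (conservative for worker protection).
#'
#' @param assessments a list of \code{\linkS4class{FrimatAssessment}}
#'   objects, or a character vector of categories.
#'
#' @return Single category string.
#' @export
aggregateActivityWorkload <- function(assessments) {
  if (!length(assessments)) stop("no assessments to aggregate")
  cats <- if (is.character(assessments)) assessments
          else vapply(assessments, workloadCategory, character(1))
  lv <- workloadCategories()
  bad <- setdiff(unique(cats), lv)
  if (length(bad)) stop("unknown workload category: ", paste(bad, collapse = ", "))
  tb <- table(factor(cats, levels = lv))   # levels ordered lightest..hardest
  hit <- which(tb == max(tb))
  lv[max(hit)]                             # tie -> hardest among modes
}

#' Score every second of a session
#'
#' Produces the per-second workload report: for each record, the activity
#' (predicted by \code{model} when given, otherwise the recorded true
#' label), the five cardiac indicators, the five coefficients, the Frimat
#' score and the qualitative category.
#'
#' @param session a \code{\linkS4class{SensorSession}} with HR on every
#'   record; records without HR are rejected.
#' @param model optional \code{\linkS4class{HARModel}} used to predict the
#'   per-second activity from the accelerometer features.
#' @param age,hrRest override the session's stored subject age / resting HR.
#'
#' @return \code{data.frame} with one row per second: timestamp, activity,
#'   true_label, the indicators, coefficients, score and category.
#' @export
scoreSession <- function(session, model = NULL,
                         age = subjectAge(session),
                         hrRest = restingHR(session)) {
  stopifnot(is(session, "SensorSession"))
  if (is.na(age) || is.na(hrRest))
    stop("subject age and resting HR are required for workload scoring")
  hr <- recordHR(session)
  if (anyNA(hr))
    stop("workload scoring requires an HR value on every record")
  activity <- if (is.null(model)) recordLabels(session) else
    predictActivities(model, featurizeSession(session, spec = {
      if (is(model, "HARModel")) featureNames(model) else fullFeatureSet()
    }))
  n <- nRecords(session)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- assessWindow(hr[i], hrRest, age)
    ind <- cardiacIndicators(a)
    cf <- frimatCoefficients(a)
    rows[[i]] <- data.frame(
      timestamp = recordTimestamps(session)[i],
      activity = activity[i],
      true_label = recordLabels(session)[i],
      acc = ind[["acc"]], rcc = ind[["rcc"]], hr_max = ind[["hr_max"]],
      hr_mean = ind[["hr_mean"]], delta_hr = ind[["delta_hr"]],
      c_acc = cf[["acc"]], c_rcc = cf[["rcc"]], c_hr_max = cf[["hr_max"]],
      c_hr_mean = cf[["hr_mean"]], c_delta_hr = cf[["delta_hr"]],
      score = frimatScoreValue(a), category = workloadCategory(a),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-activity modal workload of a scored session
#'
#' @param report the per-second report from \code{\link{scoreSession}}.
#' @return Named character vector: modal category per activity present.
#' @export
sessionWorkloadSummary <- function(report) {
  stopifnot(is.data.frame(report), all(c("activity", "category") %in% names(report)))
  acts <- sort(unique(report$activity))
  out <- vapply(acts, function(a)
    aggregateActivityWorkload(report$category[report$activity == a]),
    character(1))
  names(out) <- acts
  out
}
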