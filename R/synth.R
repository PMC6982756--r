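#' Construct an activity signal model
#'
#' Parametric model of one activity as seen by a hip-worn triaxial
#' accelerometer and a wrist HR sensor: a static gravity projection per axis
#' (posture), a single sinusoid per axis (movement cadence), additive
#' Gaussian noise, and a target HR approached by first-order relaxation.
#'
#' @param name activity name from \code{\link{activityLabels}}.
#' @param gravity length-3 gravity projection per axis (g); each component
#'   must lie in [-1, 1].
#' @param oscFreq length-3 oscillation frequency per axis (Hz).
#' @param oscAmp length-3 oscillation amplitude per axis (g), non-negative.
#' @param noiseSd standard deviation of the additive noise (g).
#' @param hrTarget steady-state HR the activity drives towards (bpm),
#'   in (40, 220).
#' @param hrTau HR relaxation time constant (s).
#'
#' @return A named list of class \code{"ActivityModel"}.
#' @export
activityModel <- function(name, gravity, oscFreq, oscAmp, noiseSd,
                          hrTarget, hrTau = 20) {
  stopifnot(name %in% activityLabels(),
            length(gravity) == 3L, all(abs(gravity) <= 1),
            length(oscFreq) == 3L, all(oscFreq >= 0),
            length(oscAmp) == 3L, all(oscAmp >= 0),
            noiseSd >= 0, hrTarget > 40, hrTarget < 220, hrTau > 0)
  structure(list(name = name, gravity = as.numeric(gravity),
                 oscFreq = as.numeric(oscFreq), oscAmp = as.numeric(oscAmp),
                 noiseSd = noiseSd, hrTarget = hrTarget, hrTau = hrTau),
            class = "ActivityModel")
}

#' Default models for the five activities
#'
#' Posture and cadence defaults chosen to reproduce the qualitative
#' contrasts the feature set separates: resting is upright and still;
#' jogging is upright with a fast (2.5 Hz) large vertical oscillation;
#' squatting is upright with a slow (0.5 Hz) vertical oscillation; push-ups
#' are prone (device z axis vertical) at 0.7 Hz; crunches are supine at
#' 0.6 Hz. HR targets grade from resting (75 bpm) up to jogging (150 bpm)
#' with a 20 s onset time constant and 1.5 bpm measurement noise (see
#' \code{\link{generateHRStream}}).
#'
#' @return Named list of five \code{ActivityModel}s.
#' @export
defaultActivityModels <- function() {
  list(
    resting = activityModel("resting", gravity = c(0, 1, 0),
      oscFreq = c(0, 0, 0), oscAmp = c(0, 0, 0),
      noiseSd = 0.02, hrTarget = 75, hrTau = 30),
    jogging = activityModel("jogging", gravity = c(0, 1, 0),
      oscFreq = c(2.5, 2.5, 2.5), oscAmp = c(0.30, 0.80, 0.25),
      noiseSd = 0.05, hrTarget = 150, hrTau = 20),
    squatting = activityModel("squatting", gravity = c(0, 1, 0),
      oscFreq = c(0.5, 0.5, 0.5), oscAmp = c(0.10, 0.40, 0.10),
      noiseSd = 0.04, hrTarget = 110, hrTau = 20),
    `push-ups` = activityModel("push-ups", gravity = c(0, 0, 1),
      oscFreq = c(0.7, 0.7, 0.7), oscAmp = c(0.10, 0.10, 0.30),
      noiseSd = 0.04, hrTarget = 125, hrTau = 20),
    crunches = activityModel("crunches", gravity = c(0, 0, -1),
      oscFreq = c(0.6, 0.6, 0.6), oscAmp = c(0.05, 0.10, 0.35),
      noiseSd = 0.04, hrTarget = 100, hrTau = 20)
  )
}

#' Define a session script
#'
#' An ordered list of (activity, duration) blocks plus subject metadata.
#' The default script is the standard test routine: push-ups, resting,
#' jogging, resting, squatting, resting, crunches, resting, each block 30 s
#' (240 s in total).
#'
#' @param activities character vector of activity names.
#' @param durations integer vector of block durations in seconds.
#' @param age subject age (years).
#' @param hrRest subject resting HR (bpm).
#'
#' @return A list of class \code{"SessionScript"}.
#' @export
sessionScript <- function(
    activities = c("push-ups", "resting", "jogging", "resting",
                   "squatting", "resting", "crunches", "resting"),
    durations = rep(30L, length(activities)),
    age = 27L, hrRest = 70) {
  stopifnot(length(activities) == length(durations),
            all(activities %in% activityLabels()),
            all(durations >= 1))
  structure(list(activities = as.character(activities),
                 durations = as.integer(durations),
                 age = as.integer(age), hrRest = as.numeric(hrRest)),
            class = "SessionScript")
}

#' Generate a synthetic accelerometer stream for one activity
#'
#' Each axis is the gravity projection plus a sinusoid (random phase per
#' axis, drawn from the seed) plus zero-mean Gaussian noise, clipped to the
#' +/-2 g sensor full scale. Deterministic per seed.
#'
#' @param model an \code{ActivityModel}.
#' @param duration_s stream duration in seconds (> 0).
#' @param rate sampling rate in Hz (default 20).
#' @param seed integer seed.
#'
#' @return (duration_s * rate) x 3 numeric matrix (columns ax, ay, az).
#' @export
generateAccelStream <- function(model, duration_s, rate = 20L, seed = 1L) {
  stopifnot(inherits(model, "ActivityModel"), duration_s > 0)
  set.seed(deriveSeed(seed, paste0("accel_", model$name)))
  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1L) / rate
  phase <- stats::runif(3L, 0, 2 * pi)
  out <- vapply(1:3, function(a) {
    x <- model$gravity[a] +
      model$oscAmp[a] * sin(2 * pi * model$oscFreq[a] * t + phase[a]) +
      stats::rnorm(n, 0, model$noiseSd)
    pmin(pmax(x, -ACCEL_FULL_SCALE), ACCEL_FULL_SCALE)
  }, numeric(n))
  if (n == 1L) out <- matrix(out, 1L, 3L)
  colnames(out) <- c("ax", "ay", "az")
  out
}

#' Generate a per-second HR stream for a session script
#'
#' First-order relaxation towards the current activity's target:
#' \code{HR[t+1] = HR[t] + (target - HR[t]) / hrTau + noise}, starting at the
#' script's resting HR, one value per second, with Gaussian measurement
#' noise (sd \code{noiseSd} bpm). Deterministic per seed.
#'
#' @param script a \code{SessionScript}.
#' @param models named list of \code{ActivityModel}s covering the script's
#'   activities.
#' @param seed integer seed.
#' @param noiseSd HR noise standard deviation in bpm (default 1.5).
#'
#' @return Numeric vector of bpm values, one per scripted second.
#' @export
generateHRStream <- function(script, models = defaultActivityModels(),
                             seed = 1L, noiseSd = 1.5) {
  stopifnot(inherits(script, "SessionScript"))
  miss <- setdiff(script$activities, names(models))
  if (length(miss)) stop("no model for activity: ", paste(miss, collapse = ", "))
  set.seed(deriveSeed(seed, "hr"))
  total <- sum(script$durations)
  perSec <- rep(script$activities, times = script$durations)
  hr <- numeric(total)
  state <- script$hrRest
  for (i in seq_len(total)) {
    m <- models[[perSec[i]]]
    state <- state + (m$hrTarget - state) / m$hrTau
    hr[i] <- state + stats::rnorm(1L, 0, noiseSd)
  }
  pmin(pmax(hr, 30), 240)   # keep within the record invariant (20, 250)
}

#' Generate a complete labelled synthetic session
#'
#' Pairs 20 accelerometer samples per second (generated block-by-block so
#' each activity keeps a continuous phase) with the 1 Hz HR stream and the
#' scripted labels; timestamps advance in strict 1000 ms steps.
#'
#' @param script a \code{SessionScript}.
#' @param models named list of \code{ActivityModel}s.
#' @param seed integer seed.
#' @param userId subject identifier string.
#' @param startTime epoch milliseconds of the first record.
#'
#' @return A \code{\linkS4class{SensorSession}} carrying the script's age
#'   and resting HR.
#' @export
generateSession <- function(script, models = defaultActivityModels(),
                            seed = 1L, userId = "synthetic-subject",
                            startTime = 1.6e12) {
  stopifnot(inherits(script, "SessionScript"))
  hr <- generateHRStream(script, models, seed = seed)
  nBlocks <- length(script$activities)
  ax <- ay <- az <- NULL
  for (b in seq_len(nBlocks)) {
    stream <- generateAccelStream(models[[script$activities[b]]],
                                  duration_s = script$durations[b],
                                  rate = SAMPLES_PER_SECOND,
                                  seed = deriveSeed(seed, paste0("block", b)))
    secs <- script$durations[b]
    ax <- rbind(ax, matrix(stream[, 1], secs, SAMPLES_PER_SECOND, byrow = TRUE))
    ay <- rbind(ay, matrix(stream[, 2], secs, SAMPLES_PER_SECOND, byrow = TRUE))
    az <- rbind(az, matrix(stream[, 3], secs, SAMPLES_PER_SECOND, byrow = TRUE))
  }
  total <- sum(script$durations)
  SensorSession(userId = userId,
                timestamp = startTime + 1000 * (seq_len(total) - 1L),
                label = rep(script$activities, times = script$durations),
                hr = hr, ax = ax, ay = ay, az = az,
                age = script$age, hrRest = script$hrRest)
}
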