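#' Read a sensor session from disk
#'
#' Reads a per-second sensor stream in either of the two supported dialects:
#' \describe{
#'   \item{jsonl}{one JSON object per line with keys \code{timestamp}
#'     (epoch ms), \code{user_id}, \code{label}, \code{hr} (or \code{null}),
#'     \code{ax}, \code{ay}, \code{az} (arrays of 20 samples in g).}
#'   \item{csv}{long format, one accelerometer sample per row with columns
#'     \code{timestamp_ms, user_id, label, hr, sample_idx, ax, ay, az};
#'     \code{sample_idx} runs 0..19 within each second.}
#' }
#' Records are ordered by timestamp on read. A malformed line raises a parse
#' error naming the line; a record without exactly 20 samples or with an
#' unknown activity label raises a validation error.
#'
#' Subject age and resting HR are session-level metadata not carried by the
#' record dialects; supply them here when the session will be workload-scored.
#'
#' @param path file to read.
#' @param format \code{"jsonl"} or \code{"csv"}.
#' @param age subject age in years (optional).
#' @param hrRest subject resting HR in bpm (optional).
#'
#' @return A \code{\linkS4class{SensorSession}}.
#' @seealso \code{\link{writeSession}}
#' @export
readSession <- function(path, format = c("jsonl", "csv"),
                        age = NA_real_, hrRest = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") readSessionJSONL(path, age, hrRest)
  else readSessionCSV(path, age, hrRest)
}

readSessionJSONL <- function(path, age, hrRest) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ts <- numeric(n); lab <- character(n); hr <- numeric(n); uid <- character(n)
  ax <- matrix(NA_real_, n, SAMPLES_PER_SECOND)
  ay <- ax; az <- ax
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("parse error at line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    validateRecord(rec, i)
    ts[i] <- as.numeric(rec$timestamp)
    uid[i] <- as.character(rec$user_id)
    lab[i] <- rec$label
    hr[i] <- if (is.null(rec$hr)) NA_real_ else as.numeric(rec$hr)
    ax[i, ] <- rec$ax; ay[i, ] <- rec$ay; az[i, ] <- rec$az
  }
  assembleSession(uid, ts, lab, hr, ax, ay, az, age, hrRest, n)
}

readSessionCSV <- function(path, age, hrRest) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "user_id", "label", "hr", "sample_idx", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(assembleSession(character(), numeric(), character(), numeric(),
                           matrix(numeric(), 0, SAMPLES_PER_SECOND),
                           matrix(numeric(), 0, SAMPLES_PER_SECOND),
                           matrix(numeric(), 0, SAMPLES_PER_SECOND),
                           age, hrRest, 0L))
  groups <- split(seq_len(nrow(df)), df$timestamp_ms)
  ord <- order(as.numeric(names(groups)))
  groups <- groups[ord]
  n <- length(groups)
  ts <- numeric(n); lab <- character(n); hr <- numeric(n); uid <- character(n)
  ax <- matrix(NA_real_, n, SAMPLES_PER_SECOND)
  ay <- ax; az <- ax
  for (i in seq_len(n)) {
    rows <- groups[[i]]
    sub <- df[rows, ]
    if (nrow(sub) != SAMPLES_PER_SECOND ||
        !identical(sort(sub$sample_idx), 0:(SAMPLES_PER_SECOND - 1)))
      stop("validation error: record at timestamp ", names(groups)[i],
           " does not hold exactly ", SAMPLES_PER_SECOND,
           " samples indexed 0..", SAMPLES_PER_SECOND - 1)
    sub <- sub[order(sub$sample_idx), ]
    rec <- list(timestamp = sub$timestamp_ms[1], user_id = sub$user_id[1],
                label = sub$label[1],
                hr = if (is.na(sub$hr[1])) NULL else sub$hr[1],
                ax = sub$ax, ay = sub$ay, az = sub$az)
    validateRecord(rec, rows[1] + 1L)  # +1 for the header line
    ts[i] <- rec$timestamp; uid[i] <- rec$user_id; lab[i] <- rec$label
    hr[i] <- if (is.null(rec$hr)) NA_real_ else rec$hr
    ax[i, ] <- rec$ax; ay[i, ] <- rec$ay; az[i, ] <- rec$az
  }
  assembleSession(uid, ts, lab, hr, ax, ay, az, age, hrRest, n)
}

validateRecord <- function(rec, line) {
  for (k in c("timestamp", "user_id", "label", "ax", "ay", "az"))
    if (is.null(rec[[k]]))
      stop("parse error at line ", line, ": missing key '", k, "'", call. = FALSE)
  for (axis in c("ax", "ay", "az"))
    if (length(rec[[axis]]) != SAMPLES_PER_SECOND)
      stop("validation error at line ", line, ": ", axis, " holds ",
           length(rec[[axis]]), " samples, expected ", SAMPLES_PER_SECOND,
           call. = FALSE)
  if (!rec$label %in% activityLabels())
    stop("validation error at line ", line, ": unknown activity label '",
         rec$label, "'", call. = FALSE)
  invisible(TRUE)
}

assembleSession <- function(uid, ts, lab, hr, ax, ay, az, age, hrRest, n) {
  if (n > 0L) {
    if (length(unique(uid)) > 1L)
      stop("validation error: records carry more than one user_id")
    o <- order(ts)
    ts <- ts[o]; lab <- lab[o]; hr <- hr[o]
    ax <- ax[o, , drop = FALSE]; ay <- ay[o, , drop = FALSE]
    az <- az[o, , drop = FALSE]
  }
  SensorSession(userId = if (n) uid[1] else "unknown",
                timestamp = ts, label = lab, hr = hr,
                ax = ax, ay = ay, az = az, age = age, hrRest = hrRest)
}

#' Write a sensor session to disk
#'
#' Serialises a session in the \code{jsonl} or \code{csv} dialect documented
#' in \code{\link{readSession}}. Numeric values are written with full double
#' precision so that writing then reading is the identity on session values.
#'
#' @param session a valid \code{\linkS4class{SensorSession}}.
#' @param path output file.
#' @param format \code{"jsonl"} or \code{"csv"}.
#'
#' @return Invisibly, \code{path}.
#' @export
writeSession <- function(session, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(is(session, "SensorSession"))
  validObject(session)
  n <- nRecords(session)
  if (format == "jsonl") {
    lines <- vapply(seq_len(n), function(i) {
      rec <- list(timestamp = session@timestamp[i], user_id = session@userId,
                  label = session@label[i], hr = session@hr[i],
                  ax = session@ax[i, ], ay = session@ay[i, ], az = session@az[i, ])
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                    na = "null", null = "null"))
    }, character(1))
    writeLines(lines, path)
  } else {
    idx <- 0:(SAMPLES_PER_SECOND - 1)
    df <- data.frame(
      timestamp_ms = rep(session@timestamp, each = SAMPLES_PER_SECOND),
      user_id = rep(session@userId, n * SAMPLES_PER_SECOND),
      label = rep(session@label, each = SAMPLES_PER_SECOND),
      hr = rep(session@hr, each = SAMPLES_PER_SECOND),
      sample_idx = rep(idx, times = n),
      ax = as.vector(t(session@ax)),
      ay = as.vector(t(session@ay)),
      az = as.vector(t(session@az)),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
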