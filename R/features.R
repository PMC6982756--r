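#' Canonical feature sets
#'
#' The full 15-feature set computed from each one-second window, in the
#' canonical order used everywhere in the package: per-axis means, standard
#' deviations, variances, mean absolute deviations, then pairwise mean
#' differences. \code{prunedFeatureSet} is the optimised 11-feature set
#' obtained by dropping the four lowest-importance features
#' (\code{mean_y}, \code{mad_y}, \code{mad_z}, \code{dmean_xy}).
#'
#' @return Character vector of feature names.
#' @export
fullFeatureSet <- function() {
  c("mean_x", "mean_y", "mean_z",
    "std_x", "std_y", "std_z",
    "var_x", "var_y", "var_z",
    "mad_x", "mad_y", "mad_z",
    "dmean_xy", "dmean_yz", "dmean_xz")
}

#' @rdname fullFeatureSet
#' @export
prunedFeatureSet <- function() {
  setdiff(fullFeatureSet(), c("mean_y", "mad_y", "mad_z", "dmean_xy"))
}

#' Segment an accelerometer stream into fixed-length windows
#'
#' Splits a time-ordered sample stream into consecutive, non-overlapping
#' windows of \code{windowLen} samples (20 at the 20 Hz sampling rate, i.e.
#' one second). A trailing incomplete group is discarded, so the number of
#' windows is \code{floor(n / windowLen)}.
#'
#' @param samples numeric n x 3 matrix of triaxial samples (columns ax, ay,
#'   az), time-ordered.
#' @param windowLen samples per window; must be >= 1.
#'
#' @return List of \code{windowLen} x 3 matrices.
#' @export
segmentWindows <- function(samples, windowLen = 20L) {
  if (length(windowLen) != 1L || is.na(windowLen) || windowLen < 1)
    stop("windowLen must be a positive integer")
  windowLen <- as.integer(windowLen)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must be an n x 3 matrix")
  k <- nrow(samples) %/% windowLen
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    w <- samples[((i - 1L) * windowLen + 1L):(i * windowLen), , drop = FALSE]
    colnames(w) <- c("ax", "ay", "az")
    w
  })
}

#' Compute the 15 statistical features of one window
#'
#' For each axis: mean, standard deviation, variance and mean absolute
#' deviation; plus the three pairwise differences of axis means. Dispersion
#' statistics use the population convention (divide by n), which keeps
#' \code{var == std^2} exact; MAD is the mean of absolute deviations from
#' the axis mean.
#'
#' @param window numeric \code{windowLen} x 3 matrix (columns ax, ay, az).
#' @param windowLen expected sample count; a window of any other length is
#'   an error.
#'
#' @return Named numeric vector of the 15 features in canonical order.
#' @export
computeFeatureVector <- function(window, windowLen = 20L) {
  window <- as.matrix(window)
  if (nrow(window) != windowLen || ncol(window) != 3L)
    stop("window must be a ", windowLen, " x 3 sample matrix")
  m <- colMeans(window)
  ctr <- sweep(window, 2L, m)
  v <- colMeans(ctr^2)     # population variance
  s <- sqrt(v)
  mad <- colMeans(abs(ctr))
  out <- c(m[1], m[2], m[3], s[1], s[2], s[3], v[1], v[2], v[3],
           mad[1], mad[2], mad[3],
           m[1] - m[2], m[2] - m[3], m[1] - m[3])
  names(out) <- fullFeatureSet()
  out
}

#' Restrict feature vectors to a feature-set specification
#'
#' Returns the features named in \code{spec}, in \code{spec} order; the
#' input is not modified. Unknown names are an error.
#'
#' @param x a \code{\linkS4class{FeatureMatrix}} or a numeric matrix with
#'   feature column names.
#' @param spec character vector of feature names to keep (e.g.
#'   \code{\link{prunedFeatureSet}()}).
#'
#' @return Object of the same class as \code{x} with the selected columns.
#' @export
pruneFeatures <- function(x, spec) {
  feat <- if (is(x, "FeatureMatrix")) x@features else as.matrix(x)
  unknown <- setdiff(spec, colnames(feat))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  kept <- feat[, spec, drop = FALSE]
  if (is(x, "FeatureMatrix")) FeatureMatrix(kept, x@labels) else kept
}

#' Featurise a session into labelled one-second feature vectors
#'
#' Computes one feature vector per \code{SecondRecord}-style record (each
#' record is exactly one 20-sample window), copying the record's activity
#' label and preserving record order.
#'
#' @param session a \code{\linkS4class{SensorSession}}.
#' @param spec feature names to retain (default: the full 15-feature set).
#'
#' @return A \code{\linkS4class{FeatureMatrix}} with one labelled row per
#'   record.
#' @export
featurizeSession <- function(session, spec = fullFeatureSet()) {
  stopifnot(is(session, "SensorSession"))
  n <- nRecords(session)
  feat <- matrix(NA_real_, n, length(fullFeatureSet()),
                 dimnames = list(NULL, fullFeatureSet()))
  for (i in seq_len(n))
    feat[i, ] <- computeFeatureVector(accelWindow(session, i))
  pruneFeatures(FeatureMatrix(feat, recordLabels(session)), spec)
}

#' Read/write feature matrices as CSV
#'
#' The on-disk form is a CSV with a header row of canonical feature names
#' plus a trailing \code{label} column.
#'
#' @param x a \code{\linkS4class{FeatureMatrix}}.
#' @param path file path.
#' @return \code{readFeatureCSV} returns a \code{FeatureMatrix};
#'   \code{writeFeatureCSV} returns \code{path} invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  stopifnot(is(x, "FeatureMatrix"))
  df <- as.data.frame(x@features)
  df$label <- x@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV must carry a label column")
  lab <- as.character(df$label)
  df$label <- NULL
  FeatureMatrix(as.matrix(df), lab)
}
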