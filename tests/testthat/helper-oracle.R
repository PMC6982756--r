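# Independent brute-force oracle: recomputes every window statistic from its
# definition by explicit summation, deliberately avoiding the vectorised
# path used by computeFeatureVector().
oracleFeatureVector <- function(window) {
  n <- nrow(window)
  means <- vars <- mads <- numeric(3)
  for (a in 1:3) {
    s <- 0
    for (i in seq_len(n)) s <- s + window[i, a]
    means[a] <- s / n
  }
  for (a in 1:3) {
    sv <- sm <- 0
    for (i in seq_len(n)) {
      d <- window[i, a] - means[a]
      sv <- sv + d * d
      sm <- sm + abs(d)
    }
    vars[a] <- sv / n
    mads[a] <- sm / n
  }
  c(mean_x = means[1], mean_y = means[2], mean_z = means[3],
    std_x = sqrt(vars[1]), std_y = sqrt(vars[2]), std_z = sqrt(vars[3]),
    var_x = vars[1], var_y = vars[2], var_z = vars[3],
    mad_x = mads[1], mad_y = mads[2], mad_z = mads[3],
    dmean_xy = means[1] - means[2], dmean_yz = means[2] - means[3],
    dmean_xz = means[1] - means[3])
}

# 1-nearest-centroid classifier used as an independent oracle for
# separable synthetic benchmarks.
nearestCentroidPredict <- function(trainFeat, trainLab, testFeat) {
  classes <- sort(unique(trainLab))
  centroids <- t(vapply(classes, function(cl)
    colMeans(trainFeat[trainLab == cl, , drop = FALSE]),
    numeric(ncol(trainFeat))))
  apply(testFeat, 1, function(v)
    classes[which.min(rowSums(sweep(centroids, 2, v)^2))])
}
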