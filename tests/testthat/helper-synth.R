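# Multi-session synthetic benchmark corpus under the default activity
# models: several runs of the standard 8 x 30 s routine, featurised and
# stacked.
makeBenchmarkCorpus <- function(seed, nSessions = 3L, spec = prunedFeatureSet()) {
  fms <- lapply(seq_len(nSessions), function(i)
    featurizeSession(
      generateSession(sessionScript(),
                      seed = harload:::deriveSeed(seed, paste0("corpus", i))),
      spec = spec))
  FeatureMatrix(do.call(rbind, lapply(fms, featureValues)),
                unlist(lapply(fms, recordLabels)))
}

# Small valid session assembled directly (no generator) for IO edge cases.
tinySession <- function(n = 3L, label = "resting", hr = 72) {
  SensorSession(userId = "u1",
                timestamp = 1.6e12 + 1000 * (seq_len(n) - 1),
                label = rep(label, n), hr = rep(hr, n),
                ax = matrix(0.01, n, 20), ay = matrix(0.99, n, 20),
                az = matrix(-0.02, n, 20), age = 30, hrRest = 65)
}
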