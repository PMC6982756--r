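# Deterministic sub-seed derivation: one user-facing seed governs data
# generation, splitting and training; each stage hashes its own tag so
# stages draw independent streams.
deriveSeed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Statistical mode of values rounded to integers; ties -> smallest value.
integerMode <- function(x) {
  x <- round(x)
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
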