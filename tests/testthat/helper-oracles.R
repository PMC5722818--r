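# Independent oracles used across the suite. These are deliberately naive
# (direct transcriptions of definitions) and stay independent of the
# package's implementations.

# exhaustive template-counting ApEn: direct enumeration of the Pincus
# definition, self-matches included, Chebyshev distance
apenOracle <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    N <- n - mm + 1
    logC <- numeric(N)
    for (i in seq_len(N)) {
      cnt <- 0L
      for (j in seq_len(N)) {
        match <- TRUE
        for (k in 0:(mm - 1)) {
          if (abs(x[i + k] - x[j + k]) > r) { match <- FALSE; break }
        }
        if (match) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / N)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# magnitude response of a designed digital filter at frequency f (Hz),
# via direct evaluation of the transfer polynomial on the unit circle
filterGainAt <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  b <- as.numeric(flt$b); a <- as.numeric(flt$a)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# closed-form first-difference mobility of a pure sinusoid
sineMobility <- function(f, fs) 2 * sin(pi * f / fs)

makeSine <- function(f, fs = 256, seconds = 60, amplitude = 1) {
  amplitude * sin(2 * pi * f * (0:(fs * seconds - 1)) / fs)
}

makeRecording <- function(data, fs = 256, ...) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  EEGRecording(data, fs = fs, ...)
}

# small cohort spec used by io/pipeline tests: 3 + 3 subjects, 1 trial,
# short recordings, single condition
smallSpec <- function(seed = 11, duration = 12, ...) {
  syntheticSpec(nHealthy = 3, nConcussed = 3, nTrials = 1,
                conditions = "EO", duration = duration, seed = seed, ...)
}

# null cohort: identical group spectra and Hurst targets
nullSpec <- function(seed, duration = 30) {
  syntheticSpec(conditions = "EO", duration = duration, seed = seed,
                concussedBinPower = referenceBinPower("healthy"),
                hurstConcussed = 0.7)
}
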