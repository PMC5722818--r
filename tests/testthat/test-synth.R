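test_that("fGn autocovariance is exact: iid limit and closed-form lag-1", {
  # H = 0.5: gamma(k) = 0 for all k >= 1
  expect_equal(fgnAutocovariance(1:20, 0.5), rep(0, 20))
  # H = 0.8: sample lag-1 autocovariance (known zero mean) matches the
  # closed form 0.5 * (2^1.6 - 2) over 200 replicates of n = 4096
  g1 <- fgnAutocovariance(1, 0.8)
  expect_equal(g1, 0.5 * (2^1.6 - 2))
  acv <- vapply(1:200, function(s) {
    x <- generateFGN(0.8, 4096, seed = s)
    mean(x[-1] * x[-length(x)])
  }, 0.0)
  expect_lt(abs(mean(acv) - g1), 0.02)
})

test_that("fGn is deterministic under seed, unit variance, validated", {
  x1 <- generateFGN(0.7, 2048, seed = 42)
  x2 <- generateFGN(0.7, 2048, seed = 42)
  expect_identical(x1, x2)
  expect_lt(abs(var(generateFGN(0.5, 2^14, seed = 1)) - 1), 0.05)
  expect_error(generateFGN(0, 1024), "hurst")
  expect_error(generateFGN(1, 1024), "hurst")
  expect_error(generateFGN(0.5, 8), "n")
})

test_that("fGn round-trips through the Hurst estimator", {
  hs <- vapply(1:5, function(s)
    hurstExponent(generateFGN(0.8, 2^14, seed = s)), 0.0)
  expect_lt(abs(mean(hs) - 0.8), 0.1)
})

test_that("shapeSpectrum hits flat per-bin targets on white noise", {
  set.seed(5)
  y <- shapeSpectrum(rnorm(256 * 260), rep(10, 40), 256)
  sp <- spectralProfile(epochRecording(makeRecording(y)))
  est <- as.numeric(binLinearPower(sp))
  expect_true(all(abs(est / 10 - 1) < 0.1))
})

test_that("shapeSpectrum concentrates power for a spiked target", {
  set.seed(6)
  tgt <- rep(1, 40); tgt[10] <- 100
  y <- shapeSpectrum(rnorm(256 * 120), tgt, 256)
  # realized long-FFT bin power equals the target exactly (the scaling
  # normalises the realisation, not just its expectation)
  n <- length(y)
  Y <- fft(y)
  f <- (1:(n / 2)) * 256 / n
  pw <- 2 * Mod(Y[2:(n / 2 + 1)])^2 / n^2
  bins <- pmin(40, floor(f + 0.5))
  keep <- f >= 0.5 & f < 40.5
  realized <- vapply(split(pw[keep], bins[keep]), sum, 0.0)
  expect_equal(unname(realized), tgt, tolerance = 1e-9)
  # windowed epoch measurement smears the spike into its neighbours but
  # still concentrates the spectrum at bin 10
  sp <- spectralProfile(epochRecording(makeRecording(y)))
  p <- as.numeric(binLinearPower(sp))
  expect_gt(p[10] / sum(p), 0.5)
  expect_gt(p[10] / p[30], 50)
})

test_that("shapeSpectrum edge cases: zero input, bad arguments", {
  expect_identical(shapeSpectrum(numeric(256 * 2) , rep(1, 40), 256),
                   numeric(512))
  expect_error(shapeSpectrum(numeric(0), rep(1, 40), 256), "zero-length")
  expect_error(shapeSpectrum(rnorm(512), rep(0, 40), 256), "positive")
})

test_that("injectArtifacts: identity at zero rates, input untouched", {
  rec <- makeRecording(matrix(rnorm(2 * 2560), 2),
                       channelLabels = c("F3", "P4"))
  out <- injectArtifacts(rec, artifactConfig(), seed = 1)
  expect_identical(eegData(out), eegData(rec))
  orig <- eegData(rec)
  out2 <- injectArtifacts(rec, artifactConfig(burstProb = 0.5), seed = 1)
  expect_identical(eegData(rec), orig)          # original unchanged
  expect_false(identical(eegData(out2), orig))
})

test_that("burst injection contaminates ~binomial number of epochs", {
  fs <- 256
  nSec <- 280
  counts <- vapply(1:3, function(s) {
    rec <- makeRecording(rnorm(fs * nSec))
    out <- injectArtifacts(rec, artifactConfig(burstProb = 0.05),
                           seed = s)
    d <- eegData(out) - eegData(rec)
    perSec <- colSums(matrix(d[1, ]^2, nrow = fs))
    sum(perSec > 0)
  }, 0.0)
  # E = 14, SD = sqrt(280 * .05 * .95) ~ 3.65; mean of 3 within 3 SD
  expect_lt(abs(mean(counts) - 14), 3 * sqrt(280 * 0.05 * 0.95))
})

test_that("line noise is attenuated by the band-pass as the filter response predicts", {
  fs <- 256
  rec <- makeRecording(rnorm(fs * 60))
  noisy <- injectArtifacts(rec, artifactConfig(lineFreq = 50,
                                               lineAmplitude = 20),
                           seed = 2)
  filt <- bandpassFilter(noisy)
  p50 <- function(r) {
    ep <- epochRecording(trimTransitions(r, 2))
    mean(vapply(seq_len(nEpochs(ep)), function(e)
      epochPSD(epochArray(ep)[e, 1, ], fs = fs, window = "rectangular",
               allBins = TRUE)[["f50"]], 0.0))
  }
  before <- p50(noisy)
  after <- p50(filt)
  # zero-phase order-4 low-pass at 40 Hz: |H(50)|^4 power attenuation
  oracle <- filterGainAt(signal::butter(4, 40 / 128, "low"), 50, fs)^4
  expect_lt(after / before, oracle * 3)
  expect_gt(before / after, 100)   # >> 6 dB in any case
})

test_that("generateCohort reproduces the study design and is deterministic", {
  spec <- syntheticSpec(duration = 2, seed = 9)
  co <- generateCohort(spec)
  expect_length(co, 189)   # 21 subjects x 3 trials x 3 conditions
  expect_identical(sort(unique(vapply(co, subjectGroup, ""))),
                   c("concussed", "healthy"))
  byGroup <- table(vapply(co, subjectGroup, ""))
  expect_equal(unname(byGroup[["healthy"]]), 14 * 9)
  expect_equal(unname(byGroup[["concussed"]]), 7 * 9)
  expect_identical(channelLabels(co[[1]]),
                   c("F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "POz"))
  expect_equal(ncol(eegData(co[[1]])), 512)
  co2 <- generateCohort(spec)
  expect_identical(eegData(co[[5]]), eegData(co2[[5]]))
  expect_error(generateCohort(syntheticSpec(nHealthy = 1)), "2 subjects")
})

test_that("cohort serialization round-trips byte-identically under a seed", {
  co <- generateCohort(smallSpec(seed = 3, duration = 2))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  writeCohort(co, d1)
  writeCohort(generateCohort(smallSpec(seed = 3, duration = 2)), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  unlink(c(d1, d2), recursive = TRUE)
})
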