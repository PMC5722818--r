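fs <- 256

test_that("Hjorth parameters match definitions and closed forms", {
  expect_equal(hjorthActivity(rep(3, 100)), 0)
  expect_error(hjorthActivity(1), "2 samples")
  # alternating (0,2,0,2,...) has population variance 1
  alt <- rep(c(0, 2), 5000)
  expect_lt(abs(hjorthActivity(alt) - 1), 1e-3)
  set.seed(20)
  expect_lt(abs(hjorthActivity(rnorm(1e4)) - 1), 0.05)
  # sinusoid mobility/complexity vs first-difference closed form, 60 s
  for (f in c(2, 10, 20, 40)) {
    s <- makeSine(f)
    expect_lt(abs(hjorthMobility(s) / sineMobility(f, fs) - 1), 0.01)
    expect_lt(abs(hjorthComplexity(s) - 1), 0.01)
  }
  expect_lt(abs(hjorthMobility(makeSine(10)) - 0.2447), 0.005)
  # mobility increases monotonically with frequency
  mob <- vapply(1:40, function(f) hjorthMobility(makeSine(f, seconds = 8)),
                0.0)
  expect_true(all(diff(mob) > 0))
  expect_error(hjorthMobility(rep(1, 100)), "constant")
  expect_error(hjorthComplexity(seq_len(100)), "diff")
})

test_that("white noise is more complex than any pure sinusoid", {
  set.seed(21)
  n <- 2560
  sineC <- vapply(c(1, 5, 10, 20, 40), function(f)
    hjorthComplexity(makeSine(f, seconds = 10)), 0.0)
  noiseC <- vapply(1:50, function(i) hjorthComplexity(rnorm(n)), 0.0)
  expect_gt(min(noiseC), max(sineC))
})

test_that("ApEn matches the exhaustive template-counting oracle", {
  # the 12-point alternating series, m = 2, r = 0.5
  x12 <- rep(c(1, 2), 6)
  expect_equal(approximateEntropy(x12, m = 2, r = 0.5),
               apenOracle(x12, 2, 0.5), tolerance = 1e-10)
  # battery: 20 seeded series of length <= 64, mixed shapes and (m, r)
  set.seed(22)
  for (i in 1:20) {
    n <- sample(20:64, 1)
    x <- switch(1 + i %% 4,
                rnorm(n),
                sin(2 * pi * 3 * seq_len(n) / n) + rnorm(n, sd = 0.2),
                cumsum(rnorm(n)),
                runif(n))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 1.5) * sd(x)
    expect_equal(approximateEntropy(x, m = m, r = r),
                 apenOracle(x, m, r), tolerance = 1e-10,
                 label = sprintf("series %d (n=%d, m=%d)", i, n, m))
  }
})

test_that("ApEn: constant series gives zero; errors on bad tolerance", {
  expect_equal(approximateEntropy(rep(1, 100), r = 0.5), 0)
  expect_error(approximateEntropy(rep(1, 100)), "positive")   # r = 2*sd = 0
  expect_error(approximateEntropy(rnorm(3), m = 2), "short")
})

test_that("a sinusoid is more regular than white noise under ApEn", {
  set.seed(23)
  n <- 2560
  wins <- 0
  for (i in 1:100) {
    phase <- runif(1, 0, 2 * pi)
    s <- sin(2 * pi * 10 * seq_len(n) / fs + phase)
    e <- rnorm(n)
    if (approximateEntropy(s) < approximateEntropy(e)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("R/S Hurst estimates are unbiased at H = 0.5 and ordered in H", {
  hs <- vapply(1:10, function(s)
    hurstExponent(generateFGN(0.5, 2^13, seed = 100 + s)), 0.0)
  expect_lt(abs(mean(hs) - 0.5), 0.05)
  means <- vapply(c(0.3, 0.5, 0.7, 0.9), function(H)
    mean(vapply(1:10, function(s)
      hurstExponent(generateFGN(H, 2^13, seed = 200 + s)), 0.0)), 0.0)
  expect_true(all(diff(means) > 0))
  expect_error(hurstExponent(rnorm(100)), "short")
  expect_error(hurstExponent(rep(1, 1024)), "zero-variance")
})

test_that("narrow-band isolation concentrates and preserves power correctly", {
  set.seed(24)
  x <- rnorm(fs * 60)
  y <- narrowbandSignal(x, center = 10, fs = fs)
  sp <- spectralProfile(epochRecording(makeRecording(y)))
  p <- as.numeric(binLinearPower(sp))
  expect_gte(p[10] / sum(p), 0.8)
  # pure 10 Hz sine through its own band: amplitude preserved within 5%
  s <- makeSine(10)
  y10 <- narrowbandSignal(s, 10, fs = fs)
  expect_lt(abs(sqrt(mean(y10^2) / mean(s^2)) - 1), 0.05)
  # through a band one octave away: at least 20 dB down
  y20 <- narrowbandSignal(s, 20, fs = fs)
  expect_lt(10 * log10(mean(y20^2) / mean(s^2)), -20)
  expect_error(narrowbandSignal(s, 50, fs = fs), "1..40")
  expect_error(narrowbandSignal(s, 30, fs = 59), "sampling rate")
})

test_that("extractFeatures enumerates the full scope grid", {
  co <- generateCohort(syntheticSpec(nHealthy = 2, nConcussed = 2,
                                     nTrials = 1, conditions = "EO",
                                     channels = "Cz", duration = 12,
                                     seed = 30))
  ep <- preprocessRecording(co[[1]], trim = 0)
  ft <- extractFeatures(ep)
  expect_equal(nrow(ft), 6 * 46)   # 6 features x (broadband + 5 + 40)
  expect_setequal(unique(ft$feature),
                  c("power", "activity", "mobility", "complexity",
                    "apen", "hurst"))
  expect_equal(sum(ft$scope == "broadband"), 6)
  expect_true(all(ft$status[ft$feature == "activity"] == "ok"))
  expect_true(all(ft$value[ft$feature == "activity" & ft$status == "ok"]
                  >= 0))
  expect_identical(ft$subject_id[1], subjectId(co[[1]]))
})

test_that("channel averaging: identical channels equal the single channel", {
  set.seed(31)
  x <- shapeSpectrum(rnorm(fs * 12), referenceBinPower("healthy"), fs)
  one <- epochRecording(makeRecording(x))
  nine <- epochRecording(makeRecording(matrix(rep(x, each = 9), nrow = 9,
                                              byrow = FALSE)))
  sel <- c("broadband", "band:alpha", "bin:10")
  f1 <- extractFeatures(one, features = c("activity", "mobility",
                                          "complexity"), scopes = sel)
  f9 <- extractFeatures(nine, features = c("activity", "mobility",
                                           "complexity"), scopes = sel)
  expect_equal(f9$value, f1$value, tolerance = 1e-10)
})

test_that("scale invariance audit across the feature set", {
  set.seed(32)
  co <- generateCohort(smallSpec(seed = 32))
  ep1 <- preprocessRecording(co[[1]], trim = 0)
  c0 <- 3
  rec2 <- EEGRecording(c0 * eegData(co[[1]]), fs = fs,
                       channelLabels = channelLabels(co[[1]]))
  ep2 <- preprocessRecording(rec2, trim = 0)
  sel <- c("broadband", "band:delta", "bin:10")
  f1 <- extractFeatures(ep1, scopes = sel)
  f2 <- extractFeatures(ep2, scopes = sel)
  v1 <- function(f) f1$value[f1$feature == f]
  v2 <- function(f) f2$value[f2$feature == f]
  expect_equal(v2("activity"), c0^2 * v1("activity"), tolerance = 1e-8)
  expect_equal(v2("power"), v1("power") + 2 * log10(c0), tolerance = 1e-8)
  for (f in c("mobility", "complexity", "hurst", "apen"))
    expect_equal(v2(f), v1(f), tolerance = 1e-8, label = f)
})

test_that("a failing feature is flagged without poisoning other rows", {
  # all-zero recording: mobility/apen/hurst degenerate, activity fine
  ep <- epochRecording(makeRecording(matrix(0, 1, fs * 10)))
  ft <- extractFeatures(ep, features = c("activity", "mobility", "apen"),
                        scopes = "broadband")
  expect_equal(ft$value[ft$feature == "activity"], 0)
  expect_true(is.na(ft$value[ft$feature == "mobility"]))
  expect_false(ft$status[ft$feature == "mobility"] == "ok")
  expect_true(is.na(ft$value[ft$feature == "apen"]))
})
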