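fs <- 256

test_that("band-pass removes DC and matches the designed response in band", {
  # DC is deep in the stop band
  rec <- makeRecording(matrix(5, 1, fs * 30))
  out <- eegData(bandpassFilter(rec))[1, (2 * fs):(28 * fs)]
  expect_lt(mean(out^2), 1e-6 * 25)
  # 10 Hz sine passes with gain 1 within 2 percent (oracle: evaluate the
  # designed cascade's response at 10 Hz, squared for zero phase)
  s10 <- makeSine(10)
  o10 <- eegData(bandpassFilter(makeRecording(s10)))[1, ]
  mid <- (5 * fs):(55 * fs)
  gain <- sqrt(mean(o10[mid]^2) / mean(s10[mid]^2))
  oracle <- filterGainAt(signal::butter(4, 1 / 128, "high"), 10, fs)^2 *
    filterGainAt(signal::butter(4, 40 / 128, "low"), 10, fs)^2
  expect_lt(abs(gain - 1), 0.02)
  expect_lt(abs(gain - oracle), 0.01)
  # 50 Hz is attenuated by at least 6 dB
  s50 <- makeSine(50)
  o50 <- eegData(bandpassFilter(makeRecording(s50)))[1, ]
  expect_lt(10 * log10(mean(o50[mid]^2) / mean(s50[mid]^2)), -6)
})

test_that("band-pass is linear and validates its arguments", {
  set.seed(2)
  x <- rnorm(fs * 10)
  ya <- eegData(bandpassFilter(makeRecording(3 * x)))[1, ]
  yb <- eegData(bandpassFilter(makeRecording(x)))[1, ]
  expect_equal(ya, 3 * yb, tolerance = 1e-9)
  expect_error(bandpassFilter(makeRecording(x, fs = 64)), "sampling rate")
  expect_error(bandpassFilter(makeRecording(x), low = 40, high = 1),
               "below")
})

test_that("trimming drops exactly the transition seconds", {
  rec <- makeRecording(rnorm(fs * 300))
  expect_equal(ncol(eegData(trimTransitions(rec))), fs * 280)
  expect_identical(trimTransitions(rec, 0), rec)
  expect_error(trimTransitions(makeRecording(rnorm(fs * 15)), 10),
               "shorter")
})

test_that("epoching yields 1-s, 256-sample epochs and drops the tail", {
  ep <- epochRecording(makeRecording(rnorm(fs * 280)))
  expect_equal(dim(epochArray(ep)), c(280, 1, 256))
  expect_true(all(retainedMask(ep)))
  ep2 <- epochRecording(makeRecording(rnorm(round(fs * 280.7))))
  expect_equal(nEpochs(ep2), 280)
  expect_error(epochRecording(makeRecording(rnorm(fs %/% 2))), "epoch")
  # epochs tile the recording in order
  rec <- makeRecording(seq_len(fs * 3))
  ep3 <- epochRecording(rec)
  expect_equal(as.numeric(epochArray(ep3)[2, 1, ]),
               as.numeric((fs + 1):(2 * fs)))
})

test_that("a single 10x-amplitude epoch among 280 is rejected on pass 1", {
  set.seed(7)
  x <- rnorm(fs * 280)
  bad <- 137
  x[((bad - 1) * fs + 1):(bad * fs)] <- 10 * x[((bad - 1) * fs + 1):(bad * fs)]
  ep <- rejectHighPowerEpochs(epochRecording(makeRecording(x)))
  expect_true(bad %in% rejectionLog(ep)[[1]])
  expect_false(retainedMask(ep)[bad])
})

test_that("clean recordings suffer near-zero false rejections", {
  set.seed(8)
  rejected <- total <- 0
  for (r in 1:100) {
    ep <- rejectHighPowerEpochs(epochRecording(makeRecording(rnorm(fs * 60))))
    rejected <- rejected + sum(!retainedMask(ep))
    total <- total + nEpochs(ep)
  }
  expect_lt(rejected / total, 0.02)
})

test_that("injected bursts are caught, clean epochs spared", {
  set.seed(9)
  hit <- miss <- falseRej <- cleanTot <- 0
  for (r in 1:5) {
    x <- rnorm(fs * 280)
    contaminated <- which(runif(280) < 0.05)
    for (s in contaminated) {
      idx <- ((s - 1) * fs + 1):(s * fs)
      x[idx] <- x[idx] + rnorm(fs, sd = 4)  # power ~17x background
    }
    ep <- rejectHighPowerEpochs(epochRecording(makeRecording(x)))
    rej <- which(!retainedMask(ep))
    hit <- hit + sum(contaminated %in% rej)
    miss <- miss + sum(!contaminated %in% rej)
    falseRej <- falseRej + sum(!rej %in% contaminated)
    cleanTot <- cleanTot + 280 - length(contaminated)
  }
  expect_gte(hit / (hit + miss), 0.95)
  expect_lte(falseRej / cleanTot, 0.02)
})

test_that("rejection is idempotent and guards the epoch floor", {
  set.seed(10)
  x <- rnorm(fs * 60)
  x[1:fs] <- x[1:fs] * 8
  ep1 <- rejectHighPowerEpochs(epochRecording(makeRecording(x)))
  ep2 <- rejectHighPowerEpochs(ep1)
  expect_identical(retainedMask(ep1), retainedMask(ep2))
  # fewer than 8 epochs at entry errors
  small <- epochRecording(makeRecording(rnorm(fs * 5)))
  expect_error(rejectHighPowerEpochs(small), "8")
})

test_that("the full conditioning chain records provenance in order", {
  co <- generateCohort(smallSpec(seed = 2, duration = 16))
  ep <- preprocessRecording(co[[1]], trim = 2)
  expect_identical(ep@provenance$pipeline,
                   c("bandpass", "trim", "epoch", "reject"))
  expect_equal(nEpochs(ep), 12)
  expect_identical(ep@provenance$subjectId, subjectId(co[[1]]))
})
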