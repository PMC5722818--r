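#' @include AllClasses.R
NULL

## cache of circulant eigenvalues keyed by (H, embedding size); the same
## (H, n) is requested thousands of times in cohort generation
.fgnCache <- new.env(parent = emptyenv())

#' Theoretical autocovariance of fractional Gaussian noise
#'
#' gamma(k) = 0.5 * (|k+1|^2H - 2|k|^2H + |k-1|^2H) for unit-variance fGn.
#' At H = 0.5 this is zero for all k >= 1 (the iid Gaussian limit).
#'
#' @param k integer lag(s), >= 0.
#' @param hurst Hurst exponent in (0, 1).
#' @return Autocovariance value(s).
#' @export
fgnAutocovariance <- function(k, hurst) {
  stopifnot(hurst > 0, hurst < 1, all(k >= 0))
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

.fgnEigen <- function(hurst, n) {
  m <- 2^ceiling(log2(2 * (n - 1)))
  key <- sprintf("%.12g_%d", hurst, m)
  lam <- .fgnCache[[key]]
  if (is.null(lam)) {
    g <- fgnAutocovariance(0:(m / 2), hurst)
    row1 <- c(g, rev(g[2:(m / 2)]))
    lam <- Re(stats::fft(row1))
    # the fGn autocovariance is positive semidefinite on the circulant
    # embedding; clip numerical negatives
    lam[lam < 0] <- 0
    .fgnCache[[key]] <- lam
  }
  lam
}

#' Generate exact fractional Gaussian noise
#'
#' Simulates a stationary Gaussian series with the exact fGn autocovariance
#' ([fgnAutocovariance()]) by circulant embedding (Davies-Harte): the
#' covariance circulant is diagonalised by the FFT, complex Gaussian
#' spectral amplitudes are drawn with variances given by its eigenvalues,
#' and an inverse transform returns a series whose population mean is 0 and
#' population variance 1. `hurst = 0.5` yields iid Gaussian noise;
#' `hurst > 0.5` long-range temporally correlated noise.
#'
#' @param hurst target Hurst exponent, in (0, 1).
#' @param n number of samples (>= 16).
#' @param seed optional integer seed. When supplied the draw is made in a
#'   temporary RNG state (the caller's stream is untouched); when `NULL`
#'   the current RNG stream is consumed, so an enclosing seed still makes
#'   the output reproducible.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- generateFGN(0.8, 1024, seed = 1)
#' var(x)  # close to 1
#' @export
generateFGN <- function(hurst, n, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("'hurst' must be a single value in (0, 1)")
  if (!is.numeric(n) || length(n) != 1L || n < 16)
    stop("'n' must be a single integer >= 16")
  n <- as.integer(n)
  draw <- function() {
    lam <- .fgnEigen(hurst, n)
    m <- length(lam)
    half <- m / 2
    z <- complex(length.out = m)
    z[1] <- sqrt(lam[1] / m) * rnorm(1L)
    z[half + 1] <- sqrt(lam[half + 1] / m) * rnorm(1L)
    u <- rnorm(half - 1L)
    v <- rnorm(half - 1L)
    j <- 2:half
    z[j] <- sqrt(lam[j] / (2 * m)) * complex(real = u, imaginary = v)
    z[m + 2L - j] <- Conj(z[j])
    Re(stats::fft(z))[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Reweight a series to target per-bin spectral power
#'
#' Rescales the discrete Fourier transform of `x` so that the realized
#' one-sided power in each 1-Hz frequency bin (bins centred on 1..40 Hz,
#' i.e. covering 0.5-40.5 Hz) equals the target expected per-epoch FFT
#' power `binPower`. Phases and the within-bin fluctuation structure of the
#' input are preserved; each bin is scaled by a single real factor. Below
#' 0.5 Hz the bin-1 density is continued (the DC component itself is
#' removed) so windowed epoch spectra stay unbiased at the lowest bin;
#' above 40.5 Hz power is rolled off quadratically from the bin-40
#' density, so the output is essentially confined to the analysed
#' 1-40 Hz range.
#'
#' Because scaling normalises the realised (not just expected) bin power,
#' the long-run average epoch spectrum of the output matches the target up
#' to FFT windowing leakage.
#'
#' @param x input series (typically [generateFGN()] output).
#' @param binPower strictly positive 40-vector of target per-bin power,
#'   microvolts squared.
#' @param fs sampling rate, Hz (> 81).
#' @return Numeric vector, same length as `x`.
#' @export
shapeSpectrum <- function(x, binPower, fs) {
  if (length(x) == 0L) stop("zero-length input")
  if (length(binPower) != .N_BINS || any(binPower <= 0))
    stop("'binPower' must be a strictly positive 40-vector")
  if (fs <= 2 * 40) stop("'fs' must exceed 80 Hz")
  if (all(x == 0)) return(x)
  n <- length(x)
  X <- stats::fft(x)
  nyq <- floor(n / 2) + 1L          # index of Nyquist (n even) / top bin
  jpos <- 2:nyq
  f <- (jpos - 1) * fs / n
  # one-sided power weights: conjugate pair counts twice except Nyquist
  w <- rep(2, length(jpos))
  if (n %% 2 == 0) w[length(w)] <- 1
  # half-up rounding so f = 0.5 falls in bin 1 (bin b covers [b-.5, b+.5))
  bin <- ifelse(f >= 0.5 & f < 40.5, pmin(.N_BINS, floor(f + 0.5)), NA)
  scale <- numeric(length(jpos))
  binScale <- rep(NA_real_, .N_BINS)
  inBand <- !is.na(bin)
  if (any(inBand)) {
    pw <- w[inBand] * Mod(X[jpos[inBand]])^2 / n^2
    cur <- vapply(split(pw, bin[inBand]), sum, 0.0)
    bs <- as.integer(names(cur))
    binScale[bs] <- ifelse(cur > 0, sqrt(binPower[bs] / cur), 0)
    scale[inBand] <- binScale[bin[inBand]]
  }
  lowEdge <- if (is.na(binScale[1])) 0 else binScale[1]
  highEdge <- if (is.na(binScale[.N_BINS])) 0 else binScale[.N_BINS]
  # continue the edge-bin density below 0.5 Hz (DC itself is removed) so
  # the windowed epoch spectrum stays unbiased at bin 1; the conditioning
  # high-pass removes true sub-delta drift downstream
  below <- which(f < 0.5)
  scale[below] <- lowEdge
  above <- which(f >= 40.5)
  scale[above] <- highEdge * (40.5 / f[above])^2
  X[jpos] <- X[jpos] * scale
  if (n %% 2 == 0) {
    mirror <- jpos[jpos < nyq]
  } else {
    mirror <- jpos
  }
  X[n + 2L - mirror] <- Conj(X[mirror])
  X[1] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Artifact configuration for the synthetic generator
#'
#' @param blinkRate blink-like frontal deflections, events per minute.
#' @param blinkAmplitude peak blink amplitude, microvolts.
#' @param lineFreq mains frequency, Hz.
#' @param lineAmplitude mains sinusoid amplitude, microvolts (0 disables).
#' @param burstProb per-epoch probability of a broadband high-amplitude
#'   burst (1-s window).
#' @param burstGain burst amplitude as a multiple of the background SD; the
#'   default 4 makes burst-epoch power at least 10x background.
#' @return Named list understood by [injectArtifacts()] and
#'   [syntheticSpec()].
#' @export
artifactConfig <- function(blinkRate = 0, blinkAmplitude = 100,
                           lineFreq = 60, lineAmplitude = 0,
                           burstProb = 0, burstGain = 4) {
  stopifnot(blinkRate >= 0, lineAmplitude >= 0,
            burstProb >= 0, burstProb <= 1, burstGain >= 0)
  list(blinkRate = blinkRate, blinkAmplitude = blinkAmplitude,
       lineFreq = lineFreq, lineAmplitude = lineAmplitude,
       burstProb = burstProb, burstGain = burstGain)
}

#' Inject synthetic artifacts into a recording
#'
#' Adds, per the configuration: broadband high-amplitude bursts in randomly
#' chosen 1-second windows (amplitude `burstGain` x the channel background
#' SD, so burst-window power is at least 10x background at the default
#' gain); a mains-frequency sinusoid on every channel (random phase per
#' channel); and low-frequency blink-like raised-cosine deflections on
#' frontal channels (labels starting with "F"). With all rates zero the
#' recording is returned unchanged. The input object is never modified.
#'
#' @param recording an [EEGRecording-class].
#' @param config list from [artifactConfig()].
#' @param seed optional integer seed (see [generateFGN()] for semantics).
#' @return A new [EEGRecording-class] with artifacts added.
#' @export
injectArtifacts <- function(recording, config = artifactConfig(),
                            seed = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  config <- utils::modifyList(artifactConfig(), config)
  if (config$blinkRate == 0 && config$lineAmplitude == 0 &&
      config$burstProb == 0)
    return(recording)
  run <- function() {
    dat <- recording@data
    fs <- recording@fs
    n <- ncol(dat)
    nch <- nrow(dat)
    secs <- floor(n / fs)
    if (config$burstProb > 0 && secs >= 1) {
      hit <- which(runif(secs) < config$burstProb)
      for (s in hit) {
        idx <- ((s - 1) * fs + 1):(s * fs)
        for (ch in seq_len(nch)) {
          bg <- stats::sd(dat[ch, ])
          dat[ch, idx] <- dat[ch, idx] +
            rnorm(length(idx), sd = config$burstGain * bg)
        }
      }
    }
    if (config$lineAmplitude > 0) {
      t <- (seq_len(n) - 1) / fs
      for (ch in seq_len(nch)) {
        phase <- runif(1, 0, 2 * pi)
        dat[ch, ] <- dat[ch, ] +
          config$lineAmplitude * sin(2 * pi * config$lineFreq * t + phase)
      }
    }
    if (config$blinkRate > 0) {
      frontal <- grep("^F", recording@channelLabels)
      nBlinks <- rbinom(1, max(1, round(n / fs / 60 * config$blinkRate * 2)),
                        0.5)
      width <- round(0.4 * fs)              # ~400 ms deflection
      pulse <- config$blinkAmplitude *
        0.5 * (1 - cos(2 * pi * seq_len(width) / width))
      if (nBlinks > 0 && length(frontal) && n > width) {
        starts <- sample.int(n - width, nBlinks, replace = TRUE)
        for (s in starts) {
          idx <- s:(s + width - 1)
          for (ch in frontal) dat[ch, idx] <- dat[ch, idx] + pulse
        }
      }
    }
    methods::initialize(recording, data = dat)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Reference two-group EEG band-power deficit profile
#'
#' Published group-level mean and SD of log10 band power (microvolts
#' squared) for healthy versus previously concussed adolescent athletes,
#' per condition (eyes open, eyes closed, vigilant task). The concussed
#' group shows elevated delta and theta and reduced alpha, beta and gamma
#' power. These values parameterise the synthetic generator's default
#' between-group effect and the package's power simulations.
#'
#' @return data.frame with columns condition, group, band, mean, sd.
#' @export
referenceBandLogPower <- function() {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  tab <- rbind(
    data.frame(condition = "EO", group = "healthy", band = bands,
               mean = c(4.33, 3.47, 3.14, 2.48, 1.95),
               sd = c(0.25, 0.33, 0.36, 0.30, 0.15)),
    data.frame(condition = "EO", group = "concussed", band = bands,
               mean = c(4.81, 3.67, 2.69, 2.14, 1.58),
               sd = c(0.34, 0.38, 0.25, 0.18, 0.21)),
    data.frame(condition = "EC", group = "healthy", band = bands,
               mean = c(4.21, 3.43, 3.22, 2.46, 1.92),
               sd = c(0.33, 0.28, 0.23, 0.26, 0.13)),
    data.frame(condition = "EC", group = "concussed", band = bands,
               mean = c(4.66, 3.59, 2.85, 2.13, 1.50),
               sd = c(0.30, 0.33, 0.34, 0.33, 0.34)),
    data.frame(condition = "VT", group = "healthy", band = bands,
               mean = c(4.22, 3.38, 3.09, 2.47, 1.97),
               sd = c(0.24, 0.49, 0.40, 0.27, 0.17)),
    data.frame(condition = "VT", group = "concussed", band = bands,
               mean = c(4.68, 3.58, 2.65, 2.08, 1.52),
               sd = c(0.45, 0.34, 0.28, 0.29, 0.21))
  )
  tab
}

#' Per-bin power targets from the reference band profile
#'
#' Expands the band-level reference profile ([referenceBandLogPower()])
#' into a 40-vector of per-bin linear power targets by holding power flat
#' within each band (exclusive band membership, see [bandMembership()]).
#' Since band power is defined as the mean of member bins' linear power, a
#' flat within-band profile reproduces the band-level log10 targets
#' exactly.
#'
#' @param group `"healthy"` or `"concussed"`.
#' @param condition `"EO"`, `"EC"` or `"VT"`.
#' @return Numeric 40-vector, microvolts squared per bin.
#' @export
referenceBinPower <- function(group = c("healthy", "concussed"),
                              condition = "EO") {
  group <- match.arg(group)
  stopifnot(condition %in% .CONDITIONS)
  ref <- referenceBandLogPower()
  ref <- ref[ref$group == group & ref$condition == condition, ]
  bands <- bandMembership("exclusive")
  out <- numeric(.N_BINS)
  for (b in names(bands))
    out[bands[[b]]] <- 10^ref$mean[ref$band == b]
  out
}

#' Construct a synthetic cohort specification
#'
#' See [SyntheticSpec-class] for slot meanings. The defaults reproduce the
#' target study design: 14 healthy and 7 concussed subjects, 3 trials under
#' 3 conditions (189 recordings), 9 channels at 256 Hz for 300 s, group
#' spectral targets from the reference deficit profile and long-range
#' temporally correlated carriers (H 0.7 healthy, 0.6 concussed).
#'
#' @param nHealthy,nConcussed subject counts.
#' @param nTrials trials per subject.
#' @param conditions recording conditions.
#' @param fs sampling rate, Hz.
#' @param duration seconds per recording.
#' @param channels channel labels.
#' @param healthyBinPower,concussedBinPower 40-vectors of per-bin power
#'   targets (microvolts squared).
#' @param hurstHealthy,hurstConcussed carrier Hurst exponents.
#' @param betweenSubjectSD per-subject whole-spectrum log10-power offset
#'   SD.
#' @param betweenSubjectShapeSD per-subject per-bin log10-power jitter SD
#'   (subject-specific spectral shape).
#' @param withinSubjectSD per-trial log10-power offset SD.
#' @param artifacts [artifactConfig()] list.
#' @param seed integer seed.
#' @return A validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(duration = 30, conditions = "EO")
#' @export
syntheticSpec <- function(nHealthy = 14L, nConcussed = 7L, nTrials = 3L,
                          conditions = c("EO", "EC", "VT"),
                          fs = 256, duration = 300,
                          channels = .CHANNELS9,
                          healthyBinPower = referenceBinPower("healthy"),
                          concussedBinPower = referenceBinPower("concussed"),
                          hurstHealthy = 0.7, hurstConcussed = 0.6,
                          betweenSubjectSD = 0.15,
                          betweenSubjectShapeSD = 0.25,
                          withinSubjectSD = 0.05,
                          artifacts = artifactConfig(), seed = 1L) {
  new("SyntheticSpec",
      nHealthy = as.integer(nHealthy), nConcussed = as.integer(nConcussed),
      nTrials = as.integer(nTrials), conditions = as.character(conditions),
      fs = as.numeric(fs), duration = as.numeric(duration),
      channels = as.character(channels),
      healthyBinPower = as.numeric(healthyBinPower),
      concussedBinPower = as.numeric(concussedBinPower),
      hurstHealthy = as.numeric(hurstHealthy),
      hurstConcussed = as.numeric(hurstConcussed),
      betweenSubjectSD = as.numeric(betweenSubjectSD),
      betweenSubjectShapeSD = as.numeric(betweenSubjectShapeSD),
      withinSubjectSD = as.numeric(withinSubjectSD),
      artifacts = artifacts, seed = as.integer(seed))
}

#' Generate a synthetic EEG cohort
#'
#' Produces one [EEGRecording-class] per subject x trial x condition. Each
#' channel is an independent fractional Gaussian noise carrier
#' ([generateFGN()]) reweighted to the subject's spectral target
#' ([shapeSpectrum()]); each subject draws a persistent whole-spectrum
#' log10-power offset (SD `betweenSubjectSD`) plus a persistent per-bin
#' shape jitter (SD `betweenSubjectShapeSD`), both applied
#' multiplicatively to its group's bin targets, and each trial an
#' additional offset (SD `withinSubjectSD`).
#' Artifacts are injected per the spec's [artifactConfig()]. The whole
#' cohort is a deterministic function of the spec (including its seed).
#'
#' @param spec a [SyntheticSpec-class], see [syntheticSpec()].
#' @return List of [EEGRecording-class] objects (healthy subjects first).
#' @examples
#' cohort <- generateCohort(syntheticSpec(
#'   nHealthy = 2, nConcussed = 2, nTrials = 1, conditions = "EO",
#'   duration = 12, seed = 7))
#' length(cohort)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- round(spec@fs * spec@duration)
  withr::with_seed(spec@seed, {
    groups <- c(rep("healthy", spec@nHealthy),
                rep("concussed", spec@nConcussed))
    ids <- c(sprintf("H%02d", seq_len(spec@nHealthy)),
             sprintf("C%02d", seq_len(spec@nConcussed)))
    subjOffset <- rnorm(length(ids), 0, spec@betweenSubjectSD)
    # persistent subject-specific spectral shape (per-bin jitter)
    subjShape <- matrix(rnorm(length(ids) * .N_BINS, 0,
                              spec@betweenSubjectShapeSD),
                        nrow = length(ids))
    out <- vector("list",
                  length(ids) * spec@nTrials * length(spec@conditions))
    k <- 0L
    hasArtifacts <- spec@artifacts$blinkRate > 0 ||
      spec@artifacts$lineAmplitude > 0 || spec@artifacts$burstProb > 0
    for (i in seq_along(ids)) {
      grp <- groups[i]
      target0 <- if (grp == "healthy") spec@healthyBinPower
                 else spec@concussedBinPower
      hurst <- if (grp == "healthy") spec@hurstHealthy
               else spec@hurstConcussed
      for (cond in spec@conditions) {
        for (tr in seq_len(spec@nTrials)) {
          trialOffset <- rnorm(1, 0, spec@withinSubjectSD)
          target <- target0 *
            10^(subjOffset[i] + subjShape[i, ] + trialOffset)
          dat <- matrix(0, nrow = length(spec@channels), ncol = n)
          for (ch in seq_along(spec@channels)) {
            carrier <- generateFGN(hurst, n)
            dat[ch, ] <- shapeSpectrum(carrier, target, spec@fs)
          }
          rec <- EEGRecording(dat, fs = spec@fs,
                              channelLabels = spec@channels,
                              subjectId = ids[i], group = grp,
                              condition = cond, trial = tr)
          if (hasArtifacts)
            rec <- injectArtifacts(rec, spec@artifacts)
          k <- k + 1L
          out[[k]] <- rec
        }
      }
    }
    out
  })
}
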