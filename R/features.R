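#' @include AllClasses.R spectral.R
NULL

#' Hjorth parameters
#'
#' The three Hjorth time-domain descriptors of a single-channel series:
#'
#' * Activity = var(x), the signal power (microvolts squared; sample
#'   variance with denominator n-1).
#' * Mobility = sqrt(var(dx) / var(x)), an RMS measure of relative
#'   frequency. The derivative is implemented as the first difference
#'   without sampling-rate scaling, so mobility is reported in
#'   radians/sample; for a sinusoid of frequency f at sampling rate fs the
#'   value is 2*sin(pi*f/fs).
#' * Complexity = Mobility(dx) / Mobility(x), a dimensionless
#'   change-of-frequency ratio that converges to one for a pure sinusoid.
#'
#' Any sampling-rate scaling of the derivative cancels in complexity,
#' which is why the unscaled first difference is used throughout.
#'
#' @param x numeric series.
#' @return A single numeric value.
#' @examples
#' t <- (0:(256 * 60 - 1)) / 256
#' hjorthComplexity(sin(2 * pi * 10 * t))  # ~1
#' @name hjorth
NULL

#' @rdname hjorth
#' @export
hjorthActivity <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  stats::var(x)
}

#' @rdname hjorth
#' @export
hjorthMobility <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples")
  v <- stats::var(x)
  if (v == 0) stop("mobility undefined for a constant series (var = 0)")
  sqrt(stats::var(diff(x)) / v)
}

#' @rdname hjorth
#' @export
hjorthComplexity <- function(x) {
  if (length(x) < 4L) stop("need at least 4 samples")
  if (stats::var(x) == 0) stop("complexity undefined: var(x) = 0")
  if (stats::var(diff(x)) == 0)
    stop("complexity undefined: var(diff(x)) = 0")
  hjorthMobility(diff(x)) / hjorthMobility(x)
}

#' Approximate entropy (Pincus ApEn)
#'
#' ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r), where Phi^m is the mean log
#' fraction of m-length templates matching within Chebyshev distance `r`
#' (self-matches included). Lower values indicate a more regular,
#' deterministic series. The tolerance defaults to `rMult` standard
#' deviations of the series; the pipeline default is `rMult = 2` (an
#' unusually wide tolerance compared with the common 0.2*SD, which
#' compresses the dynamic range of the statistic -- set `rMult = 0.2` for
#' the conventional behaviour).
#'
#' @param x numeric series (a few hundred samples or more recommended; the
#'   hard minimum is `m + 2`).
#' @param m template length (embedding dimension), default 2.
#' @param rMult tolerance as a multiple of `sd(x)`; ignored when `r` is
#'   given.
#' @param r absolute tolerance (> 0) overriding `rMult`.
#' @return ApEn in nats (non-negative up to floating-point error).
#' @examples
#' approximateEntropy(rep(1, 100), r = 0.5)  # 0: constant series
#' @export
approximateEntropy <- function(x, m = 2L, rMult = 2.0, r = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be a positive integer")
  if (length(x) < m + 2L) stop("series too short for ApEn")
  if (is.null(r)) r <- rMult * stats::sd(x)
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  apen_phi_cpp(as.numeric(x), m, r) - apen_phi_cpp(as.numeric(x), m + 1L, r)
}

# expected R/S of an iid Gaussian series of length n
# (Anis-Lloyd small-sample expectation with the Peters correction)
.expectedRSiid <- function(n) {
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  g <- if (n <= 340) exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
       else 1 / sqrt(n * pi / 2)
  (n - 0.5) / n * g * s
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classical R/S estimate of the Hurst exponent: the series is partitioned
#' into non-overlapping windows at `nSizes` logarithmically spaced sizes
#' between `minWindow` and n/4; for each window the range of the
#' mean-adjusted cumulative sum is divided by the window SD, and R/S is
#' averaged per size. With `corrected = TRUE` (the default) the estimate
#' is 0.5 plus the OLS slope of log(R/S) minus its small-sample iid
#' expectation (Anis-Lloyd-Peters) against log window size, which removes
#' the well-known upward small-sample bias of the plain statistic (a plain
#' log-log slope, available via `corrected = FALSE`, reads about 0.54 for
#' iid noise at n = 10^4). H = 0.5 indicates uncorrelated noise,
#' 0.5 < H < 1 long-range temporal correlation.
#'
#' Out-of-range estimates (outside (0, 1)) are returned as-is, not
#' clipped, so downstream consumers can flag them.
#'
#' @param x numeric series of at least 256 samples.
#' @param minWindow smallest window size (default 16).
#' @param nSizes number of window sizes (default 12, at least 10).
#' @param corrected apply the small-sample iid correction? Default `TRUE`.
#' @return Estimated Hurst exponent.
#' @examples
#' hurstExponent(rnorm(4096))  # ~0.5
#' @export
hurstExponent <- function(x, minWindow = 16L, nSizes = 12L,
                          corrected = TRUE) {
  n <- length(x)
  if (n < 256L) stop("series too short for R/S analysis (need >= 256)")
  if (nSizes < 10L) stop("need at least 10 window sizes")
  sizes <- unique(round(exp(seq(log(minWindow), log(n / 4),
                                length.out = nSizes))))
  rs <- vapply(sizes, function(w) {
    k <- n %/% w
    vals <- vapply(seq_len(k), function(i) {
      seg <- x[((i - 1) * w + 1):(i * w)]
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      y <- cumsum(seg - mean(seg))
      (max(y) - min(y)) / s
    }, 0.0)
    mean(vals, na.rm = TRUE)
  }, 0.0)
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L)
    stop("zero-variance windows dominate; R/S slope undefined")
  lw <- log(sizes[ok])
  if (corrected) {
    e0 <- vapply(sizes[ok], .expectedRSiid, 0.0)
    unname(0.5 + stats::coef(stats::lm(I(log(rs[ok]) - log(e0)) ~ lw))[2])
  } else {
    unname(stats::coef(stats::lm(log(rs[ok]) ~ lw))[2])
  }
}

# squared magnitude response of an order-`order` Butterworth band-pass at
# frequencies f (Hz); applied twice (power response) this models a
# forward-backward (zero-phase) pass
.butterBandGain2 <- function(f, low, high, order) {
  f0sq <- low * high
  bw <- high - low
  q <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + q^(2 * order))
}

#' Zero-phase spectral band-pass
#'
#' Filters a series by multiplying its DFT with the squared magnitude
#' response of an order-4 Butterworth band-pass (the magnitude a
#' forward-backward time-domain application would produce) and inverse
#' transforming. The result is exactly zero-phase, has the input's length,
#' and is numerically robust even for the 1-Hz-wide bands used by the
#' single-frequency feature analysis, where high-order IIR polynomial
#' filters are ill-conditioned.
#'
#' @param x numeric series.
#' @param low,high band edges, Hz (0 < low < high < fs/2).
#' @param fs sampling rate, Hz.
#' @param order Butterworth order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
fftBandpass <- function(x, low, high, fs, order = 4) {
  n <- length(x)
  if (n < 4L) stop("series too short")
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("band edges must satisfy 0 < low < high < fs/2")
  X <- stats::fft(x)
  nyq <- n %/% 2 + 1L
  f <- (seq_len(nyq) - 1) * fs / n
  g <- .butterBandGain2(f, low, high, order)^2   # zero-phase: |H|^2
  gain <- numeric(n)
  gain[seq_len(nyq)] <- g
  if (n %% 2 == 0) gain[(nyq + 1):n] <- rev(g[2:(nyq - 1L)])
  else gain[(nyq + 1):n] <- rev(g[2:nyq])
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

#' Isolate a 1-Hz-wide narrow-band component
#'
#' Zero-phase band-pass over `[center - width/2, center + width/2]` Hz via
#' [fftBandpass()], used to compute single-frequency features.
#'
#' @param x numeric series.
#' @param center centre frequency, Hz (1..40).
#' @param width band width, Hz (default 1).
#' @param fs sampling rate, Hz (`fs > 2 * (center + width/2)`).
#' @param order Butterworth order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
narrowbandSignal <- function(x, center, width = 1, fs, order = 4) {
  if (center < 1 || center > 40)
    stop("'center' must lie in 1..40 Hz")
  if (fs <= 2 * (center + width / 2))
    stop("sampling rate too low for the requested band")
  fftBandpass(x, center - width / 2, center + width / 2, fs, order = order)
}

.FEATURES <- c("power", "activity", "mobility", "complexity", "apen",
               "hurst")

.allScopes <- function() {
  c("broadband", paste0("band:", names(.BAND_EDGES)),
    paste0("bin:", seq_len(.N_BINS)))
}

#' Extract the feature table of one cleaned recording
#'
#' Computes every requested feature at every requested frequency scope and
#' averages across channels, emitting one long-format row per (feature,
#' scope). Scopes are `"broadband"` (the cleaned 1-40 Hz signal), the five
#' conventional bands, and the 40 single-frequency bins; time-domain and
#' nonlinear features are computed on the concatenation of the retained
#' epochs (band and bin scopes on the correspondingly filtered
#' concatenation, via [fftBandpass()]), while `power` rows come from the
#' spectral stage ([spectralProfile()]): log10 channel-mean power per bin
#' and band, and for broadband the log10 of the mean linear power over the
#' 40 bins.
#'
#' A feature that errors on any channel (for example mobility of a
#' zero-variance series) yields `NA` with the message in the `status`
#' column; other rows are unaffected.
#'
#' @param epoched an [EpochedEEG-class] with at least 8 retained epochs.
#' @param profile optional precomputed [SpectralProfile-class] (computed
#'   internally when `power` is requested and `profile` is `NULL`).
#' @param features subset of `c("power", "activity", "mobility",
#'   "complexity", "apen", "hurst")`.
#' @param scopes subset of scope labels (default all 46).
#' @param apenM,apenRMult approximate-entropy parameters, see
#'   [approximateEntropy()].
#' @param aggregate `"whole"` (default): time-domain and nonlinear
#'   features are computed once on the concatenated retained epochs;
#'   `"perEpoch"`: computed per 1-s epoch and averaged over epochs
#'   (an alternative reading of per-recording feature extraction).
#' @param convention band boundary convention, see [bandMembership()].
#' @return data.frame with columns subject_id, group, condition, trial,
#'   feature, scope, value, status.
#' @export
extractFeatures <- function(epoched, profile = NULL,
                            features = .FEATURES,
                            scopes = .allScopes(),
                            apenM = 2L, apenRMult = 2.0,
                            aggregate = c("whole", "perEpoch"),
                            convention = c("inclusive", "exclusive")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(epoched, "EpochedEEG"))
  convention <- match.arg(convention)
  features <- match.arg(features, .FEATURES, several.ok = TRUE)
  badScopes <- setdiff(scopes, .allScopes())
  if (length(badScopes))
    stop("unknown scopes: ", paste(badScopes, collapse = ", "))
  keep <- which(epoched@retainedMask)
  if (length(keep) < 8L) stop("need at least 8 retained epochs")
  fs <- epoched@fs
  nch <- dim(epoched@epochs)[2]
  len <- dim(epoched@epochs)[3]
  n <- length(keep) * len
  # concatenation of retained epochs, per channel, plus its DFT (reused by
  # every band/bin scope)
  sig <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch))
    sig[ch, ] <- as.vector(t(epoched@epochs[keep, ch, ]))
  sigFFT <- lapply(seq_len(nch), function(ch) stats::fft(sig[ch, ]))
  bands <- bandMembership(convention)

  if ("power" %in% features && is.null(profile))
    profile <- spectralProfile(epoched, convention = convention)

  applyGain <- function(ch, low, high) {
    nyq <- n %/% 2 + 1L
    f <- (seq_len(nyq) - 1) * fs / n
    g <- .butterBandGain2(f, low, high, 4)^2
    gain <- numeric(n)
    gain[seq_len(nyq)] <- g
    if (n %% 2 == 0) gain[(nyq + 1):n] <- rev(g[2:(nyq - 1L)])
    else gain[(nyq + 1):n] <- rev(g[2:nyq])
    Re(stats::fft(sigFFT[[ch]] * gain, inverse = TRUE)) / n
  }

  scopeSignal <- function(scope, ch) {
    if (scope == "broadband") return(sig[ch, ])
    if (startsWith(scope, "band:")) {
      e <- .BAND_EDGES[[sub("band:", "", scope)]]
      return(applyGain(ch, e[1], e[2]))
    }
    b <- as.integer(sub("bin:", "", scope))
    applyGain(ch, b - 0.5, b + 0.5)
  }

  timeFeature1 <- function(feat, x) {
    switch(feat,
           activity = hjorthActivity(x),
           mobility = hjorthMobility(x),
           complexity = hjorthComplexity(x),
           apen = approximateEntropy(x, m = apenM, rMult = apenRMult),
           hurst = hurstExponent(x))
  }
  timeFeature <- function(feat, x) {
    if (aggregate == "whole") return(timeFeature1(feat, x))
    starts <- seq(1L, length(x) - len + 1L, by = len)
    mean(vapply(starts, function(s)
      timeFeature1(feat, x[s:(s + len - 1L)]), 0.0))
  }

  powerValue <- function(scope) {
    if (scope == "broadband")
      return(log10(mean(colMeans(binLinearPower(profile)))))
    if (startsWith(scope, "band:"))
      return(unname(channelMeanBands(profile)[sub("band:", "", scope)]))
    unname(channelMeanBins(profile)[as.integer(sub("bin:", "", scope))])
  }

  nRows <- length(features) * length(scopes)
  outFeature <- outScope <- outStatus <- character(nRows)
  outValue <- numeric(nRows)
  idx <- 0L
  timeFeats <- setdiff(features, "power")
  for (scope in scopes) {
    chSignals <- NULL
    if (length(timeFeats))
      chSignals <- lapply(seq_len(nch), function(ch) scopeSignal(scope, ch))
    for (feat in features) {
      status <- "ok"
      if (feat == "power") {
        val <- tryCatch(powerValue(scope),
                        error = function(e) { status <<- conditionMessage(e)
                                              NA_real_ })
      } else {
        val <- tryCatch(
          mean(vapply(chSignals, function(x) timeFeature(feat, x), 0.0)),
          error = function(e) { status <<- conditionMessage(e); NA_real_ })
      }
      idx <- idx + 1L
      outFeature[idx] <- feat
      outScope[idx] <- scope
      outValue[idx] <- val
      outStatus[idx] <- status
    }
  }
  data.frame(
    subject_id = epoched@provenance$subjectId %||% NA_character_,
    group = epoched@provenance$group %||% NA_character_,
    condition = epoched@provenance$condition %||% NA_character_,
    trial = epoched@provenance$trial %||% NA_integer_,
    feature = outFeature, scope = outScope, value = outValue,
    status = outStatus, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
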