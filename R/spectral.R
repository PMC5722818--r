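#' @include AllClasses.R
NULL

.BAND_EDGES <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                    beta = c(12, 30), gamma = c(30, 40))

#' Tapered-cosine (Tukey) window
#'
#' A rectangular window whose first and last `taper/2` fraction are raised
#' cosine tapers; `taper = 0` is rectangular, `taper = 1` a Hann window.
#' The spectral estimator uses a 10% total taper.
#'
#' @param n window length.
#' @param taper total taper fraction in \[0, 1\].
#' @return Numeric vector of length `n`.
#' @export
tukeyWindow <- function(n, taper = 0.1) {
  stopifnot(n >= 1, taper >= 0, taper <= 1)
  if (taper == 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(taper * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:(edge - 1)
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (taper * (n - 1)) - 1)))
    w[1:edge] <- ramp
    w[n:(n - edge + 1)] <- ramp
  }
  w
}

#' One-sided FFT power of a 1-second epoch
#'
#' Computes the single-epoch power spectrum: the epoch (one channel,
#' exactly `fs` samples so bins fall on integer frequencies) is multiplied
#' by a tapered-cosine window with 10% total taper, transformed, and
#' one-sided power is corrected for the window's power loss (division by
#' the mean squared window) so that white-noise power is unbiased. A pure
#' unit sinusoid on a bin centre then shows up with power within a few
#' percent of A^2/2.
#'
#' @param epoch numeric vector of exactly `fs` samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param taperFraction total taper fraction (default 0.1).
#' @param window `"tukey"` (default) or `"rectangular"` (test mode: with
#'   `allBins = TRUE` the returned powers satisfy Parseval's identity,
#'   summing to the epoch's mean squared amplitude).
#' @param allBins return all one-sided bins 0..fs/2 instead of 1..40 Hz.
#' @return Named numeric vector of linear power (microvolts squared): bins
#'   1..40 Hz, or 0..fs/2 when `allBins`.
#' @examples
#' p <- epochPSD(sin(2 * pi * 10 * (0:255) / 256), fs = 256)
#' which.max(p)  # bin 10
#' @export
epochPSD <- function(epoch, fs = 256, taperFraction = 0.1,
                     window = c("tukey", "rectangular"), allBins = FALSE) {
  window <- match.arg(window)
  n <- round(fs)
  if (length(epoch) != n)
    stop(sprintf("epoch must hold exactly %d samples (1 s at %g Hz)", n, fs))
  w <- if (window == "tukey") tukeyWindow(n, taperFraction) else rep(1, n)
  X <- stats::fft(epoch * w)
  corr <- mean(w^2)
  nyq <- n %/% 2
  p <- Mod(X[1:(nyq + 1)])^2 / (n^2 * corr)
  p[2:nyq] <- 2 * p[2:nyq]          # fold conjugate pairs; DC and Nyquist once
  if (allBins) {
    names(p) <- paste0("f", 0:nyq)
    p
  } else {
    out <- p[2:(.N_BINS + 1)]       # integer frequencies 1..40 Hz
    names(out) <- paste0("bin_", seq_len(.N_BINS))
    out
  }
}

#' Band membership of 1-Hz bins
#'
#' Maps each conventional band (delta 1-4, theta 4-8, alpha 8-12, beta
#' 12-30, gamma 30-40 Hz) to its member integer bins. The band notation
#' leaves the shared boundary frequencies (4, 8, 12, 30 Hz) ambiguous; the
#' default `"inclusive"` convention assigns each boundary bin to both
#' adjacent bands, while `"exclusive"` treats bands as half-open `[a, b)`.
#' Gamma always includes both 30 and 40 Hz. The convention in force is
#' stamped into every [SpectralProfile-class] and report.
#'
#' @param convention `"inclusive"` (default) or `"exclusive"`.
#' @return Named list of integer bin vectors covering 1..40.
#' @examples
#' bandMembership()$delta       # 1 2 3 4
#' bandMembership("exclusive")$delta  # 1 2 3
#' @export
bandMembership <- function(convention = c("inclusive", "exclusive")) {
  convention <- match.arg(convention)
  out <- lapply(.BAND_EDGES, function(e) {
    if (convention == "inclusive") seq.int(e[1], e[2])
    else seq.int(e[1], e[2] - 1L)
  })
  out$gamma <- seq.int(30L, 40L)
  out
}

#' Average per-epoch bin power and take logs
#'
#' The aggregation rule of the spectral stage: per-bin linear power is
#' averaged over epochs first, band linear power is the mean of member
#' bins' linear power, and logs (base 10) are taken last. This is the
#' "average then log" order; [SpectralProfile-class] accessors expose the
#' log views while the linear intermediates stay recomputable.
#'
#' @param perEpochBins epochs x 40 matrix of linear bin power for one
#'   channel.
#' @param bands band membership list from [bandMembership()].
#' @return List with `bin` (40-vector, linear) and `band` (per-band
#'   linear power).
#' @export
averageAndLog <- function(perEpochBins, bands = bandMembership()) {
  perEpochBins <- rbind(perEpochBins)
  if (nrow(perEpochBins) < 1L) stop("no retained epochs to average")
  if (ncol(perEpochBins) != .N_BINS)
    stop("expected 40 bin columns")
  binLin <- colMeans(perEpochBins)
  bandLin <- vapply(bands, function(b) mean(binLin[b]), 0.0)
  list(bin = binLin, band = bandLin)
}

#' Spectral profile of an epoched recording
#'
#' Estimates per-channel linear power for the 40 1-Hz bins and the 5
#' conventional bands from the retained epochs: [epochPSD()] per epoch and
#' channel, averaged over epochs, bands as means of member bins
#' ([averageAndLog()]). Only retained epochs enter the average.
#'
#' @param epoched an [EpochedEEG-class] with at least one retained epoch.
#' @param taperFraction window taper fraction, see [epochPSD()].
#' @param convention band boundary convention, see [bandMembership()].
#' @return A [SpectralProfile-class].
#' @export
spectralProfile <- function(epoched, taperFraction = 0.1,
                            convention = c("inclusive", "exclusive")) {
  stopifnot(is(epoched, "EpochedEEG"))
  convention <- match.arg(convention)
  keep <- which(epoched@retainedMask)
  if (!length(keep)) stop("no retained epochs")
  bands <- bandMembership(convention)
  nch <- dim(epoched@epochs)[2]
  binPower <- matrix(0, nrow = nch, ncol = .N_BINS)
  bandPower <- matrix(0, nrow = nch, ncol = length(bands))
  n <- round(epoched@fs)
  w <- tukeyWindow(n, taperFraction)
  corr <- mean(w^2)
  for (ch in seq_len(nch)) {
    # columns = epochs; one multivariate FFT replaces per-epoch calls
    segs <- matrix(aperm(epoched@epochs[keep, ch, , drop = FALSE],
                         c(3, 1, 2)), nrow = n) * w
    X <- stats::mvfft(segs)
    per <- t(2 * Mod(X[2:(.N_BINS + 1), , drop = FALSE])^2 / (n^2 * corr))
    agg <- averageAndLog(per, bands)
    binPower[ch, ] <- agg$bin
    bandPower[ch, ] <- agg$band
  }
  rownames(binPower) <- rownames(bandPower) <- epoched@channelLabels
  colnames(binPower) <- paste0("bin_", seq_len(.N_BINS))
  colnames(bandPower) <- names(bands)
  new("SpectralProfile", binPower = binPower, bandPower = bandPower,
      bands = bands, convention = convention,
      nEpochsUsed = length(keep),
      meta = list(window = "tukey", taperFraction = taperFraction,
                  logBase = 10, channelLabels = epoched@channelLabels))
}

#' Serialise a spectral profile
#'
#' Writes the per-channel log10 power table (rows = channels, columns =
#' `bin_1..bin_40` then the five bands) as CSV, plus a JSON sidecar with
#' the estimation metadata (window family, taper fraction, log base, band
#' convention and membership, number of epochs used).
#'
#' @param profile a [SpectralProfile-class].
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
writeSpectralProfile <- function(profile, path) {
  stopifnot(is(profile, "SpectralProfile"))
  tab <- cbind(data.frame(channel = rownames(binLinearPower(profile)),
                          stringsAsFactors = FALSE),
               as.data.frame(binLogPower(profile)),
               as.data.frame(bandLogPower(profile)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- c(profile@meta,
            list(convention = profile@convention,
                 bands = profile@bands,
                 nEpochsUsed = profile@nEpochsUsed))
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
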