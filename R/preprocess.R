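#' @include AllClasses.R
NULL

.butterCascade <- function(low, high, fs, order = 4) {
  # separate high-pass and low-pass quarters are numerically safer than a
  # single narrow band-pass polynomial and match a 6*order dB/octave edge
  list(hp = signal::butter(order, low / (fs / 2), type = "high"),
       lp = signal::butter(order, high / (fs / 2), type = "low"))
}

# forward-backward (zero-phase) IIR with odd-symmetric edge reflection,
# as in the usual filtfilt construction; x is sample x channel
.zeroPhase <- function(flt, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  n <- nrow(x)
  npad <- min(3L * (max(length(a), length(b)) - 1L) * 10L, n - 1L)
  pre <- 2 * rep(x[1, ], each = npad) - x[(npad + 1):2, , drop = FALSE]
  post <- 2 * rep(x[n, ], each = npad) -
    x[(n - 1):(n - npad), , drop = FALSE]
  y <- iir_filter_cpp(b, a, rbind(pre, x, post))
  y <- iir_filter_cpp(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(npad + 1):(npad + n), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 1-40 Hz, 4th order per edge,
#' i.e. 24 dB/octave roll-off) as a cascade of a high-pass and a low-pass
#' section, each run forward-backward with odd-symmetric edge reflection,
#' so the output is zero-phase and features downstream are not
#' phase-distorted. Pass-band
#' centre gain is unity to well within 0.5 dB.
#'
#' @param recording an [EEGRecording-class].
#' @param low,high band edges, Hz (`low < high`, `fs > 2 * high`).
#' @param order filter order per edge (default 4).
#' @return A filtered [EEGRecording-class].
#' @examples
#' rec <- EEGRecording(matrix(rnorm(256 * 20), 1), fs = 256)
#' filtered <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(recording, low = 1, high = 40, order = 4) {
  stopifnot(is(recording, "EEGRecording"))
  if (low >= high) stop("'low' must be below 'high'")
  if (recording@fs <= 2 * high)
    stop("sampling rate too low for the requested band (need fs > 2*high)")
  flt <- .butterCascade(low, high, recording@fs, order)
  y <- .zeroPhase(flt$hp, t(recording@data))
  y <- .zeroPhase(flt$lp, y)
  methods::initialize(recording, data = t(y))
}

#' Trim state-transition segments
#'
#' Drops the first and last `trim` seconds of a recording to remove
#' state-transition effects (the conditioning protocol drops 10 s at each
#' end of a 5-minute recording, leaving 280 s).
#'
#' @param recording an [EEGRecording-class].
#' @param trim seconds to drop at each end (default 10).
#' @return The interior [EEGRecording-class].
#' @export
trimTransitions <- function(recording, trim = 10) {
  stopifnot(is(recording, "EEGRecording"), trim >= 0)
  if (trim == 0) return(recording)
  n <- ncol(recording@data)
  cut <- round(trim * recording@fs)
  if (n <= 2 * cut)
    stop("recording shorter than twice the trim length")
  methods::initialize(recording,
                      data = recording@data[, (cut + 1):(n - cut),
                                            drop = FALSE])
}

#' Segment a recording into 1-second epochs
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `round(fs)` samples (256 at 256 Hz); a trailing partial second is
#' discarded. All epochs are initially marked retained.
#'
#' @param recording an [EEGRecording-class] of at least 1 s.
#' @return An [EpochedEEG-class].
#' @export
epochRecording <- function(recording) {
  stopifnot(is(recording, "EEGRecording"))
  len <- round(recording@fs)
  n <- ncol(recording@data)
  nEp <- n %/% len
  if (nEp < 1L) stop("recording shorter than one epoch (1 s)")
  nch <- nrow(recording@data)
  ep <- array(0, dim = c(nEp, nch, len))
  for (e in seq_len(nEp))
    ep[e, , ] <- recording@data[, ((e - 1) * len + 1):(e * len)]
  new("EpochedEEG", epochs = ep, fs = recording@fs,
      channelLabels = recording@channelLabels,
      retainedMask = rep(TRUE, nEp), rejectionLog = list(),
      provenance = list(subjectId = recording@subjectId,
                        group = recording@group,
                        condition = recording@condition,
                        trial = recording@trial))
}

.epochPowers <- function(epoched) {
  # broadband epoch power: mean squared amplitude pooled over channels
  apply(epoched@epochs^2, 1, mean)
}

#' Reject high-power epochs (iterative 3-SD rule)
#'
#' Implements the amplitude-artifact rejection rule: an epoch is rejected
#' when its broadband power (mean squared amplitude, pooled over channels)
#' is at least `k` standard deviations above the mean power of the
#' currently retained ("clean") epochs. Because the clean set is only
#' defined by the rule itself, the threshold is re-estimated iteratively on
#' the survivors until no epoch exceeds it (or `maxIter` passes), which
#' makes the operation idempotent. Each pass's rejected epoch indices are
#' appended to the rejection log.
#'
#' @param epoched an [EpochedEEG-class] with at least 8 retained epochs.
#' @param k SD multiplier (default 3).
#' @param maxIter iteration cap (default 10).
#' @return The [EpochedEEG-class] with an updated mask and log.
#' @export
rejectHighPowerEpochs <- function(epoched, k = 3, maxIter = 10) {
  stopifnot(is(epoched, "EpochedEEG"), k > 0, maxIter >= 1)
  if (sum(epoched@retainedMask) < 8L)
    stop("fewer than 8 retained epochs at entry; recording unusable")
  p <- .epochPowers(epoched)
  mask <- epoched@retainedMask
  log <- epoched@rejectionLog
  for (pass in seq_len(maxIter)) {
    mu <- mean(p[mask])
    sdev <- stats::sd(p[mask])
    bad <- which(mask & p >= mu + k * sdev)
    if (!length(bad)) break
    if (sum(mask) - length(bad) < 8L)
      stop("fewer than 8 epochs would survive rejection; recording unusable")
    mask[bad] <- FALSE
    log <- c(log, list(bad))
  }
  methods::initialize(epoched, retainedMask = mask, rejectionLog = log)
}

#' Run the full signal-conditioning chain
#'
#' Convenience wrapper applying, in order: [bandpassFilter()],
#' [trimTransitions()], [epochRecording()] and [rejectHighPowerEpochs()].
#' The order is recorded in the provenance of the result.
#'
#' @param recording an [EEGRecording-class].
#' @param low,high,order band-pass parameters, see [bandpassFilter()].
#' @param trim seconds trimmed at each end, see [trimTransitions()].
#' @param k,maxIter rejection parameters, see [rejectHighPowerEpochs()].
#' @return An [EpochedEEG-class] ready for [spectralProfile()] and
#'   [extractFeatures()].
#' @export
preprocessRecording <- function(recording, low = 1, high = 40, order = 4,
                                trim = 10, k = 3, maxIter = 10) {
  rec <- bandpassFilter(recording, low = low, high = high, order = order)
  rec <- trimTransitions(rec, trim = trim)
  ep <- epochRecording(rec)
  ep <- rejectHighPowerEpochs(ep, k = k, maxIter = maxIter)
  ep@provenance$pipeline <- c("bandpass", "trim", "epoch", "reject")
  ep@provenance$params <- list(low = low, high = high, order = order,
                               trim = trim, k = k, maxIter = maxIter)
  ep
}
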