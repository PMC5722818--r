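#' @include eegdeficits-package.R
NULL

.GROUPS <- c("healthy", "concussed")
.CONDITIONS <- c("EO", "EC", "VT")
.CHANNELS9 <- c("F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "POz")
.N_BINS <- 40L

#' Multi-channel EEG recording
#'
#' Container for one continuous EEG trace (channels x samples, microvolts)
#' with acquisition metadata and cohort labels (subject, group, condition,
#' trial). Group is `"healthy"` or `"concussed"`; condition is one of
#' `"EO"` (eyes open), `"EC"` (eyes closed) or `"VT"` (vigilant task).
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of `data`.
#' @slot subjectId subject identifier.
#' @slot group `"healthy"` or `"concussed"`.
#' @slot condition `"EO"`, `"EC"` or `"VT"`.
#' @slot trial trial index (integer, 1-based).
#'
#' @seealso [EEGRecording()] for the constructor.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    group = "character",
    condition = "character",
    trial = "integer"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data must have exactly one row per channel label")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite samples")
  if (!object@group %in% .GROUPS)
    msg <- c(msg, sprintf("group must be one of: %s",
                          paste(.GROUPS, collapse = ", ")))
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of: %s",
                          paste(.CONDITIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (microvolts), or a numeric
#'   vector for a single channel.
#' @param fs sampling rate, Hz.
#' @param channelLabels channel labels; defaults to `Ch1..ChK`.
#' @param subjectId subject identifier.
#' @param group `"healthy"` or `"concussed"`.
#' @param condition `"EO"`, `"EC"` or `"VT"`.
#' @param trial trial index.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 512), 2), fs = 256)
#' duration(rec)
#' @export
EEGRecording <- function(data, fs, channelLabels = NULL,
                         subjectId = "S1", group = "healthy",
                         condition = "EO", trial = 1L) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (is.null(channelLabels)) {
    channelLabels <- if (!is.null(rownames(data))) rownames(data)
                     else paste0("Ch", seq_len(nrow(data)))
  }
  new("EEGRecording", data = unname(data), fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      subjectId = as.character(subjectId), group = as.character(group),
      condition = as.character(condition), trial = as.integer(trial))
}

#' Epoched EEG recording
#'
#' A recording segmented into fixed one-second epochs with a retained /
#' rejected mask. `epochs` is an epoch x channel x sample array; the mask
#' marks epochs that survived artifact rejection. `rejectionLog` holds, per
#' rejection pass, the indices of epochs rejected on that pass.
#'
#' @slot epochs numeric array, epoch x channel x sample.
#' @slot fs sampling rate, Hz.
#' @slot channelLabels channel labels.
#' @slot retainedMask logical, one entry per epoch.
#' @slot rejectionLog list of integer vectors (one per rejection pass).
#' @slot provenance list: source recording metadata and processing steps.
#' @exportClass EpochedEEG
setClass("EpochedEEG",
  representation(
    epochs = "array",
    fs = "numeric",
    channelLabels = "character",
    retainedMask = "logical",
    rejectionLog = "list",
    provenance = "list"
  )
)

setValidity("EpochedEEG", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "second dimension must match channelLabels")
    if (d[3] != round(object@fs))
      msg <- c(msg, "each epoch must hold exactly round(fs) samples (1 s)")
    if (d[1] != length(object@retainedMask))
      msg <- c(msg, "retainedMask length must equal epoch count")
  }
  if (length(msg)) msg else TRUE
})

#' Per-channel spectral profile
#'
#' Linear FFT power per 1-Hz bin (bins centred on 1..40 Hz) and per
#' conventional band (delta, theta, alpha, beta, gamma), per channel.
#' Linear intermediates are stored; log10 views and channel means are
#' provided by accessors ([binLogPower()], [bandLogPower()],
#' [channelMeanBins()], [channelMeanBands()]).
#'
#' @slot binPower channel x 40 matrix of linear power, microvolts squared.
#' @slot bandPower channel x 5 matrix of linear band power (mean of member
#'   bins' linear power).
#' @slot bands named list mapping band name to member bin integers.
#' @slot convention `"inclusive"` (boundary bins shared by adjacent bands)
#'   or `"exclusive"` (half-open bands).
#' @slot nEpochsUsed number of retained epochs averaged.
#' @slot meta list: window family, taper fraction, log base, channel labels.
#' @exportClass SpectralProfile
setClass("SpectralProfile",
  representation(
    binPower = "matrix",
    bandPower = "matrix",
    bands = "list",
    convention = "character",
    nEpochsUsed = "integer",
    meta = "list"
  )
)

setValidity("SpectralProfile", function(object) {
  msg <- character()
  if (ncol(object@binPower) != .N_BINS)
    msg <- c(msg, "binPower must have 40 columns (1..40 Hz)")
  if (ncol(object@bandPower) != length(object@bands))
    msg <- c(msg, "bandPower must have one column per band")
  if (nrow(object@binPower) != nrow(object@bandPower))
    msg <- c(msg, "binPower and bandPower must share the channel dimension")
  # band linear power must be recomputable from member bins
  for (b in names(object@bands)) {
    expect <- rowMeans(object@binPower[, object@bands[[b]], drop = FALSE])
    got <- object@bandPower[, match(b, names(object@bands))]
    if (any(abs(expect - got) > 1e-8 * (abs(expect) + 1e-300)))
      msg <- c(msg, sprintf("band '%s' is not the mean of its member bins", b))
  }
  if (length(msg)) msg else TRUE
})

#' Two-group deficit report
#'
#' Aggregated output of the statistical stage: per (feature, scope,
#' condition) test results (group means and SDs, test used, raw and
#' Bonferroni-adjusted p-values), maximal contiguous significant frequency
#' ranges per feature and condition, a band-level summary table, and a
#' provenance block (configuration hash, seed, per-recording rejection
#' counts).
#'
#' @slot results data.frame of per-scope test results.
#' @slot ranges data.frame of maximal significant bin runs.
#' @slot bandTable data.frame, band-level group summary.
#' @slot meta provenance list.
#' @exportClass DeficitReport
setClass("DeficitReport",
  representation(
    results = "data.frame",
    ranges = "data.frame",
    bandTable = "data.frame",
    meta = "list"
  )
)

#' Synthetic cohort specification
#'
#' Parameters of the synthetic EEG cohort generator. Defaults emulate the
#' study design the pipeline targets: 14 healthy vs 7 concussed subjects,
#' 3 trials each under 3 conditions, 9 channels at 256 Hz for 300 s, with
#' group mean band log-powers following the eyes-open condition of the
#' reference deficit profile (elevated delta and reduced alpha, beta and
#' gamma power in the concussed group).
#'
#' Per-bin targets are expected per-epoch linear FFT power in microvolts
#' squared for bins centred on 1..40 Hz. `betweenSubjectSD` is the SD of a
#' persistent per-subject offset in log10 power; `withinSubjectSD` the SD
#' of an additional per-trial offset.
#'
#' @slot nHealthy,nConcussed subject counts (each must be at least 2).
#' @slot nTrials trials per subject.
#' @slot conditions subset of `c("EO","EC","VT")`.
#' @slot fs sampling rate, Hz.
#' @slot duration recording duration, seconds.
#' @slot channels channel labels.
#' @slot healthyBinPower,concussedBinPower 40-vectors of target mean
#'   per-bin power, microvolts squared.
#' @slot hurstHealthy,hurstConcussed target Hurst exponent of the carrier
#'   noise, in (0, 1).
#' @slot betweenSubjectSD per-subject log10-power offset SD (a scalar
#'   level shift applied to the whole spectrum).
#' @slot betweenSubjectShapeSD SD of an additional persistent per-subject,
#'   per-bin log10-power jitter (subject-specific spectral shape).
#' @slot withinSubjectSD per-trial log10-power offset SD.
#' @slot artifacts artifact configuration list, see [artifactConfig()].
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nHealthy = "integer",
    nConcussed = "integer",
    nTrials = "integer",
    conditions = "character",
    fs = "numeric",
    duration = "numeric",
    channels = "character",
    healthyBinPower = "numeric",
    concussedBinPower = "numeric",
    hurstHealthy = "numeric",
    hurstConcussed = "numeric",
    betweenSubjectSD = "numeric",
    betweenSubjectShapeSD = "numeric",
    withinSubjectSD = "numeric",
    artifacts = "list",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nHealthy < 2L || object@nConcussed < 2L)
    msg <- c(msg, "need at least 2 subjects per group")
  if (!all(object@conditions %in% .CONDITIONS))
    msg <- c(msg, "conditions must be a subset of EO, EC, VT")
  if (length(object@healthyBinPower) != .N_BINS ||
      length(object@concussedBinPower) != .N_BINS)
    msg <- c(msg, "bin power targets must be 40-vectors")
  if (any(object@healthyBinPower <= 0) || any(object@concussedBinPower <= 0))
    msg <- c(msg, "all power targets must be strictly positive")
  for (h in c(object@hurstHealthy, object@hurstConcussed))
    if (h <= 0 || h >= 1) msg <- c(msg, "Hurst targets must lie in (0, 1)")
  if (object@fs <= 2 * 40)
    msg <- c(msg, "fs must exceed 80 Hz (Nyquist for the 1-40 Hz range)")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (length(msg)) msg else TRUE
})
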