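#' @include AllClasses.R
NULL

#' Accessors for eegdeficits classes
#'
#' Small accessor generics: `eegData()` returns the channels x samples
#' matrix; `samplingRate()` the sampling rate in Hz; `channelLabels()` the
#' channel label vector; `subjectId()`, `subjectGroup()`,
#' `recordingCondition()` and `trialIndex()` the cohort labels;
#' `duration()` the recording length in seconds; `nEpochs()` and
#' `retainedMask()` the epoch count and retained/rejected mask of an
#' [EpochedEEG-class]; `rejectionLog()` the per-pass rejection indices.
#'
#' @param x an eegdeficits object.
#' @return The corresponding slot value (see Description).
#' @name accessors
#' @aliases eegData samplingRate channelLabels subjectId subjectGroup
#'   recordingCondition trialIndex duration nEpochs retainedMask
#'   rejectionLog
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), 1), fs = 256)
#' samplingRate(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))
#' @rdname accessors
#' @export
setGeneric("recordingCondition",
           function(x) standardGeneric("recordingCondition"))
#' @rdname accessors
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))
#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(x) standardGeneric("rejectionLog"))

#' Spectral profile accessors
#'
#' `binLinearPower()` / `bandLinearPower()` return the stored channel x bin
#' (or band) linear power matrices; `binLogPower()` / `bandLogPower()` their
#' log10 views; `channelMeanBins()` / `channelMeanBands()` the arithmetic
#' mean of the per-channel log10 values across channels; `nEpochsUsed()`
#' the number of retained epochs that entered the average.
#'
#' @param x a [SpectralProfile-class].
#' @return A matrix (per-channel accessors), a named numeric vector
#'   (channel means) or an integer count.
#' @name spectral-accessors
#' @aliases binLinearPower bandLinearPower binLogPower bandLogPower
#'   channelMeanBins channelMeanBands nEpochsUsed
NULL

#' @rdname spectral-accessors
#' @export
setGeneric("binLinearPower", function(x) standardGeneric("binLinearPower"))
#' @rdname spectral-accessors
#' @export
setGeneric("bandLinearPower", function(x) standardGeneric("bandLinearPower"))
#' @rdname spectral-accessors
#' @export
setGeneric("binLogPower", function(x) standardGeneric("binLogPower"))
#' @rdname spectral-accessors
#' @export
setGeneric("bandLogPower", function(x) standardGeneric("bandLogPower"))
#' @rdname spectral-accessors
#' @export
setGeneric("channelMeanBins", function(x) standardGeneric("channelMeanBins"))
#' @rdname spectral-accessors
#' @export
setGeneric("channelMeanBands", function(x) standardGeneric("channelMeanBands"))
#' @rdname spectral-accessors
#' @export
setGeneric("nEpochsUsed", function(x) standardGeneric("nEpochsUsed"))

#' Deficit report accessors
#'
#' `deficitResults()` returns the per-(feature, scope, condition) test
#' table; `deficitRanges()` the maximal contiguous significant frequency
#' ranges; `deficitBands()` the band-level summary table;
#' `reportMeta()` the provenance block.
#'
#' @param x a [DeficitReport-class].
#' @return A data.frame (or list for `reportMeta`).
#' @name report-accessors
#' @aliases deficitResults deficitRanges deficitBands reportMeta
NULL

#' @rdname report-accessors
#' @export
setGeneric("deficitResults", function(x) standardGeneric("deficitResults"))
#' @rdname report-accessors
#' @export
setGeneric("deficitRanges", function(x) standardGeneric("deficitRanges"))
#' @rdname report-accessors
#' @export
setGeneric("deficitBands", function(x) standardGeneric("deficitBands"))
#' @rdname report-accessors
#' @export
setGeneric("reportMeta", function(x) standardGeneric("reportMeta"))
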