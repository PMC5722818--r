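#' @include AllGenerics.R
NULL

## ---- EEGRecording ----

#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectGroup", "EEGRecording", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("recordingCondition", "EEGRecording", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("trialIndex", "EEGRecording", function(x) x@trial)
#' @rdname accessors
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channel(s) x %d samples (%.1f s at %g Hz)\n",
    nrow(object@data), ncol(object@data), duration(object), object@fs))
  cat(sprintf("  subject %s | %s | %s | trial %d\n", object@subjectId,
              object@group, object@condition, object@trial))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
})

## ---- EpochedEEG ----

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedEEG", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochedEEG", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochedEEG", function(x) dim(x@epochs)[1])
#' @rdname accessors
#' @export
setMethod("retainedMask", "EpochedEEG", function(x) x@retainedMask)
#' @rdname accessors
#' @export
setMethod("rejectionLog", "EpochedEEG", function(x) x@rejectionLog)

setMethod("show", "EpochedEEG", function(object) {
  cat(sprintf(
    "EpochedEEG: %d epoch(s) x %d channel(s) x %d samples, %d retained\n",
    dim(object@epochs)[1], dim(object@epochs)[2], dim(object@epochs)[3],
    sum(object@retainedMask)))
  if (length(object@rejectionLog))
    cat(sprintf("  rejection passes: %d (rejected %d epoch(s))\n",
                length(object@rejectionLog),
                length(unlist(object@rejectionLog))))
})

#' Epoch array of an EpochedEEG
#'
#' @param x an [EpochedEEG-class].
#' @param retainedOnly drop rejected epochs?
#' @return epoch x channel x sample array.
#' @export
epochArray <- function(x, retainedOnly = FALSE) {
  stopifnot(is(x, "EpochedEEG"))
  if (retainedOnly) x@epochs[x@retainedMask, , , drop = FALSE] else x@epochs
}

## ---- SpectralProfile ----

#' @rdname spectral-accessors
#' @export
setMethod("binLinearPower", "SpectralProfile", function(x) x@binPower)
#' @rdname spectral-accessors
#' @export
setMethod("bandLinearPower", "SpectralProfile", function(x) x@bandPower)
#' @rdname spectral-accessors
#' @export
setMethod("binLogPower", "SpectralProfile", function(x) log10(x@binPower))
#' @rdname spectral-accessors
#' @export
setMethod("bandLogPower", "SpectralProfile", function(x) log10(x@bandPower))
#' @rdname spectral-accessors
#' @export
setMethod("channelMeanBins", "SpectralProfile", function(x) {
  v <- colMeans(log10(x@binPower))
  names(v) <- paste0("bin_", seq_len(ncol(x@binPower)))
  v
})
#' @rdname spectral-accessors
#' @export
setMethod("channelMeanBands", "SpectralProfile", function(x) {
  v <- colMeans(log10(x@bandPower))
  names(v) <- names(x@bands)
  v
})
#' @rdname spectral-accessors
#' @export
setMethod("nEpochsUsed", "SpectralProfile", function(x) x@nEpochsUsed)

setMethod("show", "SpectralProfile", function(object) {
  cat(sprintf(
    "SpectralProfile: %d channel(s), %d bins, %d bands (%s convention), %d epoch(s)\n",
    nrow(object@binPower), ncol(object@binPower), length(object@bands),
    object@convention, object@nEpochsUsed))
  cat("  channel-mean band log10 power:\n")
  print(round(channelMeanBands(object), 3))
})

## ---- DeficitReport ----

#' @rdname report-accessors
#' @export
setMethod("deficitResults", "DeficitReport", function(x) x@results)
#' @rdname report-accessors
#' @export
setMethod("deficitRanges", "DeficitReport", function(x) x@ranges)
#' @rdname report-accessors
#' @export
setMethod("deficitBands", "DeficitReport", function(x) x@bandTable)
#' @rdname report-accessors
#' @export
setMethod("reportMeta", "DeficitReport", function(x) x@meta)

setMethod("show", "DeficitReport", function(object) {
  r <- object@results
  cat(sprintf("DeficitReport: %d comparison(s), %d feature(s), %d condition(s)\n",
              nrow(r), length(unique(r$feature)),
              length(unique(r$condition))))
  if (nrow(object@ranges)) {
    cat("  significant frequency ranges:\n")
    for (i in seq_len(nrow(object@ranges))) {
      rr <- object@ranges[i, ]
      cat(sprintf("    %s / %s / %s: %s\n", rr$condition, rr$feature,
                  rr$adjust, rr$ranges))
    }
  } else cat("  no significant frequency ranges\n")
})
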