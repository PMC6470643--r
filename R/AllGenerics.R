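#' Accessors for EEG containers
#'
#' Small accessor generics shared by [EEGRecording-class] and
#' [EpochSet-class]: sampling rate, channel labels/count, subject id and the
#' clinical class label (0 = coma-like, 1 = death-like, NA = unlabelled).
#'
#' @param object an `EEGRecording` or `EpochSet`.
#' @return The corresponding slot value.
#' @name eeg-accessors
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname eeg-accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname eeg-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname eeg-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname eeg-accessors
#' @export
setGeneric("subjectLabel", function(object) standardGeneric("subjectLabel"))

#' @rdname eeg-accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @rdname eeg-accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' Segment a recording into non-overlapping epochs
#'
#' @param rec an [EEGRecording-class].
#' @param epochSeconds epoch length in seconds.
#' @param nEpochs number of epochs to keep; when `NULL`, the maximal whole
#'   number of epochs is taken and the leftover tail discarded.
#' @return An [EpochSet-class].
#' @export
setGeneric("segmentEpochs", function(rec, epochSeconds, nEpochs = NULL)
  standardGeneric("segmentEpochs"))

#' Zero-phase band-pass filtering
#'
#' @param x a numeric vector or an [EpochSet-class].
#' @param ... passed on to methods; see [bandpassFilter,numeric-method].
#' @export
setGeneric("bandpassFilter", function(x, ...) standardGeneric("bandpassFilter"))

setMethod("samplingRate", "EEGRecording", function(object) object@fs)
setMethod("samplingRate", "EpochSet", function(object) object@fs)
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
setMethod("nChannels", "EEGRecording", function(object) nrow(object@data))
setMethod("nChannels", "EpochSet", function(object) dim(object@epochs)[2L])
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
setMethod("subjectId", "EpochSet", function(object) object@subjectId)
setMethod("subjectLabel", "EEGRecording", function(object) object@label)
setMethod("subjectLabel", "EpochSet", function(object) object@label)
setMethod("signalData", "EEGRecording", function(object) object@data)
setMethod("signalData", "EpochSet", function(object) object@epochs)
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)%s\n",
    object@subjectId, nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs,
    if (is.na(object@label)) "" else sprintf(", class %d", object@label)
  ))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet '%s': %d epoch(s) x %d channel(s) x %d samples @ %g Hz%s%s\n",
    object@subjectId, d[1L], d[2L], d[3L], object@fs,
    if (is.na(object@band)) "" else sprintf(", band %s", object@band),
    if (is.na(object@label)) "" else sprintf(", class %d", object@label)
  ))
})

setMethod("show", "CCAFusion", function(object) {
  cat(sprintf(
    "CCAFusion: %d subjects, r = %d canonical pair(s)\n",
    nrow(object@Z), length(object@correlations)
  ))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", object@correlations), collapse = ", "), "\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport (leave-one-out SVM, Gaussian kernel)\n")
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              object@tp, object@fn, object@tn, object@fp))
  cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f | AUC %.4f\n",
              object@accuracy, object@sensitivity, object@specificity,
              object@auc))
})
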