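#' @import methods
#' @importFrom stats fft pf sd var rnorm runif prcomp
NULL

#' EEGRecording: a multichannel EEG recording
#'
#' Container for one subject's raw multichannel signal. Rows of `data` are
#' channels, columns are samples (microvolt-scale arbitrary units). The class
#' label, when present, encodes the clinical group: 0 = coma-like,
#' 1 = death-like (the positive class for sensitivity).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per channel.
#' @slot subjectId subject identifier.
#' @slot label integer class label in {0, 1}, or NA when unlabelled.
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    label = "integer"
  ),
  prototype(label = NA_integer_)
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "'data' must be a numeric matrix")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "'fs' must be a single positive number")
  }
  if (nrow(object@data) < 1L || ncol(object@data) < 2L) {
    msg <- c(msg, "'data' needs at least 1 channel and 2 samples")
  }
  if (length(object@channelLabels) != nrow(object@data)) {
    msg <- c(msg, sprintf(
      "length of 'channelLabels' (%d) does not match channel count (%d)",
      length(object@channelLabels), nrow(object@data)
    ))
  }
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L))) {
    msg <- c(msg, "'label' must be a single value in {0, 1} or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix (channels x samples).
#' @param fs sampling rate in Hz.
#' @param channelLabels channel names; default "ch1".."chK".
#' @param subjectId subject identifier string.
#' @param label optional class label (0 = coma-like, 1 = death-like).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), fs = 100)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, fs, channelLabels = NULL,
                         subjectId = "subject", label = NA) {
  data <- as.matrix(data)
  if (is.null(channelLabels)) {
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  }
  new("EEGRecording",
    data = data, fs = as.numeric(fs),
    channelLabels = as.character(channelLabels),
    subjectId = as.character(subjectId), label = as.integer(label)
  )
}

#' EpochSet: non-overlapping epochs of a recording
#'
#' Holds contiguous, non-overlapping segments of one subject's recording as a
#' 3-d array (epoch x channel x sample), optionally band-pass filtered (the
#' `band` slot then records the sub-band name).
#'
#' @slot epochs numeric array, nEpochs x channels x samplesPerEpoch.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels channel names.
#' @slot subjectId subject identifier.
#' @slot label class label in {0, 1} or NA.
#' @slot band name of the sub-band the epochs were filtered to, or NA.
#'
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    label = "integer",
    band = "character"
  ),
  prototype(label = NA_integer_, band = NA_character_)
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) {
    msg <- c(msg, "'epochs' must be a 3-d array (epoch x channel x sample)")
  } else {
    if (length(object@channelLabels) != d[2L]) {
      msg <- c(msg, "channelLabels length must equal the channel dimension")
    }
    if (d[3L] < 2L) msg <- c(msg, "epochs must contain at least 2 samples")
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "'fs' must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' SynthCohortSpec: parameters of the synthetic two-class cohort
#'
#' Describes the stated world of the synthetic generator: per-class band-power
#' weight profiles over the six canonical sub-bands and per-class broadband
#' noise fractions controlling pattern diversity. See [generateCohort()].
#'
#' @slot nSubjectsPerClass subjects per class.
#' @slot nChannels channel count (default 6, the frontal montage).
#' @slot fs sampling rate in Hz (default 1000).
#' @slot epochSeconds epoch length in seconds (default 60).
#' @slot epochsPerSubject epochs per subject (default 5).
#' @slot classProfiles 2 x 6 matrix of band-power weights (rows = classes),
#'   each row non-negative and summing to 1.
#' @slot classNoiseFraction length-2 vector in [0, 1]; fraction of broadband
#'   white noise mixed into each class's signal.
#' @slot subjectWeightSd lognormal sd of per-subject band-weight jitter.
#' @slot subjectNoiseSd logit-scale sd of per-subject noise-fraction jitter.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SynthCohortSpec",
  representation(
    nSubjectsPerClass = "integer",
    nChannels = "integer",
    fs = "numeric",
    epochSeconds = "numeric",
    epochsPerSubject = "integer",
    classProfiles = "matrix",
    classNoiseFraction = "numeric",
    subjectWeightSd = "numeric",
    subjectNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SynthCohortSpec", function(object) {
  msg <- character()
  if (object@nSubjectsPerClass < 1L) msg <- c(msg, "'nSubjectsPerClass' must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "'nChannels' must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "'fs' must be positive")
  if (object@epochSeconds <= 0) msg <- c(msg, "'epochSeconds' must be positive")
  if (object@epochsPerSubject < 1L) msg <- c(msg, "'epochsPerSubject' must be >= 1")
  if (!all(dim(object@classProfiles) == c(2L, 6L))) {
    msg <- c(msg, "'classProfiles' must be a 2 x 6 matrix (classes x bands)")
  } else {
    if (any(object@classProfiles < 0)) {
      msg <- c(msg, "'classProfiles' weights must be non-negative")
    }
    s <- rowSums(object@classProfiles)
    if (any(abs(s - 1) > 1e-9)) {
      msg <- c(msg, "each row of 'classProfiles' must sum to 1 (within 1e-9)")
    }
  }
  if (length(object@classNoiseFraction) != 2L ||
      any(object@classNoiseFraction < 0 | object@classNoiseFraction > 1)) {
    msg <- c(msg, "'classNoiseFraction' must be two values in [0, 1]")
  }
  if (object@subjectWeightSd < 0 || object@subjectNoiseSd < 0) {
    msg <- c(msg, "subject variability sds must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' CCAFusion: canonical correlation feature fusion result
#'
#' Result of the compact-SVD canonical correlation construction on two
#' feature views. `Z = [X | Y]` horizontally concatenates the canonical
#' projections of both views (the fused discriminative features); `Z` has
#' `2 * r` columns with `r = min(rank(A), rank(B))`.
#'
#' @slot X canonical projection of view A (subjects x r).
#' @slot Y canonical projection of view B (subjects x r).
#' @slot Z fused matrix `[X | Y]` (subjects x 2r).
#' @slot WA,WB projection matrices applied to the centred views.
#' @slot correlations canonical correlations, non-increasing, in [0, 1].
#' @slot centerA,centerB column means removed from each view.
#'
#' @export
setClass("CCAFusion",
  representation(
    X = "matrix", Y = "matrix", Z = "matrix",
    WA = "matrix", WB = "matrix",
    correlations = "numeric",
    centerA = "numeric", centerB = "numeric"
  )
)

setValidity("CCAFusion", function(object) {
  msg <- character()
  r <- length(object@correlations)
  if (ncol(object@Z) != 2L * r) {
    msg <- c(msg, "Z must have exactly 2r columns")
  }
  if (any(object@correlations < -1e-9 | object@correlations > 1 + 1e-9)) {
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  }
  if (is.unsorted(rev(object@correlations), strictly = FALSE)) {
    msg <- c(msg, "canonical correlations must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' ClassifierReport: leave-one-out SVM evaluation summary
#'
#' Confusion counts and derived metrics from leave-one-out cross-validation,
#' with per-subject decision scores (pooled across folds to form the ROC) and
#' the hyperparameters chosen in each fold.
#'
#' @slot tp,tn,fp,fn confusion counts at decision threshold 0.
#' @slot sensitivity TP / (TP + FN), the true-positive rate for the
#'   death-like class.
#' @slot specificity TN / (FP + TN).
#' @slot accuracy (TP + TN) / n.
#' @slot auc area under the ROC curve of the pooled decision scores.
#' @slot scores per-subject decision values from the fold in which the
#'   subject was left out.
#' @slot labels true class labels (0/1).
#' @slot foldParams data.frame of (C, gamma) chosen per fold.
#'
#' @export
setClass("ClassifierReport",
  representation(
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    sensitivity = "numeric", specificity = "numeric",
    accuracy = "numeric", auc = "numeric",
    scores = "numeric", labels = "integer",
    foldParams = "data.frame"
  )
)

setValidity("ClassifierReport", function(object) {
  ok <- function(x) length(x) == 1L && (is.na(x) || (x >= 0 && x <= 1))
  msg <- character()
  if (!ok(object@sensitivity) || !ok(object@specificity) ||
      !ok(object@accuracy) || !ok(object@auc)) {
    msg <- c(msg, "metrics must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
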