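#' Canonical EEG sub-band table
#'
#' The six sub-bands used throughout the package, with the conventional gaps
#' between theta/alpha (7-8 Hz), alpha/beta (12-13 Hz) and gamma1/gamma2
#' (40-41 Hz) left as-is. Intervals are treated as closed-open
#' `[low, high)`. Relative-power denominators use the full 0.5-100 Hz range,
#' not the union of the bands.
#'
#' @return A data.frame with columns `band`, `low`, `high` (Hz).
#' @examples
#' eegBands()
#' @export
eegBands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"),
    low  = c(0.5, 4, 8, 13, 30, 41),
    high = c(4, 7, 12, 30, 40, 100),
    stringsAsFactors = FALSE
  )
}

#' @describeIn segmentEpochs Split a recording into non-overlapping epochs
#'   starting at sample 0; the leftover tail is discarded. Errors if the
#'   recording is shorter than one epoch.
#' @export
setMethod("segmentEpochs", "EEGRecording",
  function(rec, epochSeconds, nEpochs = NULL) {
    spe <- round(epochSeconds * rec@fs)
    nAvail <- ncol(rec@data) %/% spe
    if (nAvail < 1L) {
      stop(sprintf(
        "recording '%s' (%d samples) is shorter than one %g-s epoch (%d samples)",
        rec@subjectId, ncol(rec@data), epochSeconds, spe
      ))
    }
    if (is.null(nEpochs)) {
      nEpochs <- nAvail
    } else if (nEpochs > nAvail) {
      stop(sprintf(
        "requested %d epochs but only %d fit into recording '%s'",
        nEpochs, nAvail, rec@subjectId
      ))
    }
    ep <- array(NA_real_, c(nEpochs, nrow(rec@data), spe))
    for (e in seq_len(nEpochs)) {
      ep[e, , ] <- rec@data[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
    }
    new("EpochSet",
      epochs = ep, fs = rec@fs, channelLabels = rec@channelLabels,
      subjectId = rec@subjectId, label = rec@label
    )
  }
)

## Zero-phase FFT-domain band-pass: amplitude mask with raised-cosine
## transitions of half-width `transitionHz` centred on each band edge
## (half-amplitude at the edge). Exactly linear and zero-phase.
fftBandpassWeights <- function(n, fs, fLow, fHigh, transitionHz = 0.5) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  twL <- min(transitionHz, fLow)
  twH <- min(transitionHz, max(fs / 2 - fHigh, 1e-12))
  up <- ifelse(f <= fLow - twL, 0,
        ifelse(f >= fLow + twL, 1,
               0.5 * (1 - cos(pi * (f - (fLow - twL)) / (2 * twL)))))
  if (twL == 0) up <- as.numeric(f >= fLow)
  down <- ifelse(f <= fHigh - twH, 1,
          ifelse(f >= fHigh + twH, 0,
                 0.5 * (1 + cos(pi * (f - (fHigh - twH)) / (2 * twH)))))
  up * down
}

fftBandpassVector <- function(x, fs, fLow, fHigh, transitionHz = 0.5) {
  n <- length(x)
  w <- fftBandpassWeights(n, fs, fLow, fHigh, transitionHz)
  Re(fft(fft(x) * w, inverse = TRUE)) / n
}

#' @describeIn bandpassFilter Filter a numeric vector sampled at `fs` to the
#'   band `[fLow, fHigh)` Hz with a zero-phase FFT-domain mask whose
#'   raised-cosine transitions have half-width `transitionHz` (half-amplitude
#'   at the band edges).
#' @param fs sampling rate in Hz (numeric method only).
#' @param fLow,fHigh band edges in Hz; either explicit values or taken from
#'   `band`.
#' @param band a band name from [eegBands()] (alternative to explicit edges).
#' @param transitionHz transition half-width in Hz.
#' @export
setMethod("bandpassFilter", "numeric",
  function(x, fs, fLow = NULL, fHigh = NULL, band = NULL, transitionHz = 0.5) {
    if (!is.null(band)) {
      bt <- eegBands()
      i <- match(band, bt$band)
      if (is.na(i)) stop("unknown band name: ", band)
      fLow <- bt$low[i]; fHigh <- bt$high[i]
    }
    if (is.null(fLow) || is.null(fHigh)) {
      stop("either 'band' or both 'fLow' and 'fHigh' must be given")
    }
    if (!(fLow > 0 && fLow < fHigh)) stop("need 0 < fLow < fHigh")
    if (fHigh > fs / 2 + 1e-9) {
      stop(sprintf("band edge %g Hz exceeds Nyquist frequency %g Hz",
                   fHigh, fs / 2))
    }
    fftBandpassVector(x, fs, fLow, fHigh, transitionHz)
  }
)

#' @describeIn bandpassFilter Filter every epoch and channel of an
#'   [EpochSet-class]; returns a copy tagged with the band name, the input is
#'   unmodified.
#' @export
setMethod("bandpassFilter", "EpochSet",
  function(x, fLow = NULL, fHigh = NULL, band = NULL, transitionHz = 0.5) {
    if (!is.null(band)) {
      bt <- eegBands()
      i <- match(band, bt$band)
      if (is.na(i)) stop("unknown band name: ", band)
      fLow <- bt$low[i]; fHigh <- bt$high[i]
      bandName <- band
    } else {
      bandName <- sprintf("%g-%g", fLow, fHigh)
    }
    if (is.null(fLow) || is.null(fHigh)) {
      stop("either 'band' or both 'fLow' and 'fHigh' must be given")
    }
    if (fHigh > x@fs / 2 + 1e-9) {
      stop(sprintf("band edge %g Hz exceeds Nyquist frequency %g Hz",
                   fHigh, x@fs / 2))
    }
    d <- dim(x@epochs)
    n <- d[3L]
    w <- fftBandpassWeights(n, x@fs, fLow, fHigh, transitionHz)
    out <- x@epochs
    for (e in seq_len(d[1L])) {
      for (ch in seq_len(d[2L])) {
        xi <- out[e, ch, ]
        out[e, ch, ] <- Re(fft(fft(xi) * w, inverse = TRUE)) / n
      }
    }
    initialize(x, epochs = out, band = bandName)
  }
)

#' Optional pre-processing hook
#'
#' Clinical pipelines remove artifacts with ICA-based tools before feature
#' extraction; that step is out of scope here. This hook offers a no-op
#' (default) or a 0.5 Hz high-pass detrend in its place.
#'
#' @param rec an [EEGRecording-class].
#' @param method `"none"` (default) or `"highpass"` (zero-phase 0.5 Hz
#'   high-pass).
#' @return The (possibly filtered) recording.
#' @export
preprocessHook <- function(rec, method = c("none", "highpass")) {
  method <- match.arg(method)
  if (method == "none") return(rec)
  ny <- rec@fs / 2
  out <- t(apply(rec@data, 1L, fftBandpassVector,
                 fs = rec@fs, fLow = 0.5, fHigh = ny * 0.999,
                 transitionHz = 0.25))
  initialize(rec, data = out)
}
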