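## Integer ordinal-pattern codes for all embedded vectors of x.
## Ranks are assigned stably (ties broken by order of occurrence), so
## permuting equal values never changes a pattern.
ordinalPatternCodes <- function(x, m, tau) {
  n <- length(x)
  nVec <- n - (m - 1L) * tau
  E <- matrix(NA_real_, nVec, m)
  for (j in seq_len(m)) {
    E[, j] <- x[seq_len(nVec) + (j - 1L) * tau]
  }
  code <- integer(nVec)
  base <- 1L
  for (j in seq_len(m)) {
    rj <- integer(nVec)
    for (kk in seq_len(m)) {
      if (kk == j) next
      if (kk < j) {
        rj <- rj + (E[, kk] <= E[, j])
      } else {
        rj <- rj + (E[, kk] < E[, j])
      }
    }
    code <- code + rj * base
    base <- base * m
  }
  code
}

#' Permutation entropy of a time series
#'
#' Shannon entropy of the distribution of ordinal rank patterns of length
#' `m` (lag `tau`) over all embedded vectors of the series. Only observed
#' patterns contribute (0 log 0 = 0). Ties are broken by order of
#' occurrence (stable ranking); optionally a tiny seeded jitter can be
#' applied instead.
#'
#' @param x numeric vector of length at least `(m - 1) * tau + 2`.
#' @param m ordinal pattern length (order), 2..10.
#' @param tau embedding lag, >= 1.
#' @param base logarithm base; `exp(1)` (nats, default) or `2` (bits).
#' @param normalize divide by `log(m!)` so the result lies in [0, 1].
#' @param tieBreak `"order"` (stable, default) or `"jitter"` (adds seeded
#'   noise of relative magnitude 1e-10 before ranking).
#' @param jitterSeed seed used when `tieBreak = "jitter"`.
#' @return Permutation entropy in `[0, log(m!)]` (or [0, 1] if normalised).
#' @examples
#' permutationEntropy(1:100, m = 3)            # monotone: exactly 0
#' permutationEntropy(rnorm(1000), m = 3)      # close to log(6)
#' @export
permutationEntropy <- function(x, m = 4, tau = 1, base = exp(1),
                               normalize = FALSE,
                               tieBreak = c("order", "jitter"),
                               jitterSeed = 1L) {
  tieBreak <- match.arg(tieBreak)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L || m > 10L) stop("'m' must be an integer in [2, 10]")
  if (tau < 1L) stop("'tau' must be >= 1")
  if (anyNA(x)) stop("input contains missing values")
  if (length(x) < (m - 1L) * tau + 2L) {
    stop(sprintf(
      "series too short: need at least %d samples for m = %d, tau = %d",
      (m - 1L) * tau + 2L, m, tau
    ))
  }
  if (tieBreak == "jitter") {
    set.seed(jitterSeed)
    sc <- max(abs(x), 1)
    x <- x + rnorm(length(x), sd = 1e-10 * sc)
  }
  code <- ordinalPatternCodes(x, m, tau)
  counts <- tabulate(code + 1L, nbins = m^m)
  pr <- counts[counts > 0L] / length(code)
  h <- -sum(pr * log(pr)) / log(base)
  if (normalize) h / (log(factorial(m)) / log(base)) else h
}

#' Time-varying permutation entropy
#'
#' Splits the series into consecutive non-overlapping windows and returns
#' the permutation entropy of each, the monitoring form used to track
#' complexity changes over time. Specify the window either as a number of
#' windows or as a window length in samples; any leftover tail is discarded.
#'
#' @inheritParams permutationEntropy
#' @param nWindows number of equal windows (mutually exclusive with
#'   `windowSamples`).
#' @param windowSamples window length in samples.
#' @return A data.frame with `window`, `start` (first sample index) and `pe`.
#' @export
timeVaryingPE <- function(x, m = 4, tau = 1, nWindows = NULL,
                          windowSamples = NULL, base = exp(1),
                          normalize = FALSE) {
  if (is.null(nWindows) == is.null(windowSamples)) {
    stop("give exactly one of 'nWindows' or 'windowSamples'")
  }
  n <- length(x)
  if (!is.null(nWindows)) {
    windowSamples <- n %/% nWindows
  }
  windowSamples <- as.integer(windowSamples)
  if (windowSamples < (m - 1L) * tau + 2L) {
    stop(sprintf("window of %d samples too short for m = %d, tau = %d",
                 windowSamples, m, tau))
  }
  nw <- n %/% windowSamples
  starts <- (seq_len(nw) - 1L) * windowSamples + 1L
  pe <- vapply(starts, function(s) {
    permutationEntropy(x[s:(s + windowSamples - 1L)], m = m, tau = tau,
                       base = base, normalize = normalize)
  }, numeric(1))
  data.frame(window = seq_len(nw), start = starts, pe = pe)
}

#' Broadband permutation entropy features of an EpochSet
#'
#' @param eps an [EpochSet-class].
#' @inheritParams permutationEntropy
#' @return A data.frame: `subject`, `label`, `epoch`, `channel`, `pe`.
#' @export
complexityFeatures <- function(eps, m = 4, tau = 1, base = exp(1),
                               normalize = FALSE) {
  d <- dim(eps@epochs)
  grid <- expand.grid(epoch = seq_len(d[1L]), channel = seq_len(d[2L]))
  pe <- mapply(function(e, ch) {
    permutationEntropy(eps@epochs[e, ch, ], m = m, tau = tau, base = base,
                       normalize = normalize)
  }, grid$epoch, grid$channel)
  data.frame(
    subject = eps@subjectId, label = eps@label, epoch = grid$epoch,
    channel = eps@channelLabels[grid$channel], pe = pe,
    stringsAsFactors = FALSE
  )
}

#' Per-band permutation entropy of an EpochSet
#'
#' Band-pass filters the epochs to each sub-band (see [bandpassFilter()])
#' and computes the permutation entropy per epoch, channel and band.
#'
#' @param eps an [EpochSet-class].
#' @param bands band table as from [eegBands()].
#' @inheritParams permutationEntropy
#' @return A data.frame: `subject`, `label`, `epoch`, `channel`, `band`,
#'   `pe`.
#' @export
pePerBand <- function(eps, bands = eegBands(), m = 4, tau = 1,
                      base = exp(1), normalize = FALSE) {
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    filt <- bandpassFilter(eps, fLow = bands$low[b], fHigh = bands$high[b])
    out <- complexityFeatures(filt, m = m, tau = tau, base = base,
                              normalize = normalize)
    out$band <- bands$band[b]
    out
  })
  do.call(rbind, rows)
}
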