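## Biased autocovariance c_0..c_p of a (already demeaned) vector.
biasedAutocov <- function(x, p) {
  n <- length(x)
  vapply(0:p, function(k) {
    sum(x[seq_len(n - k)] * x[(k + 1L):n]) / n
  }, numeric(1))
}

## Levinson-Durbin recursion on autocovariances c_0..c_p. Returns the AR
## coefficients in the generative convention x(n) = sum_k a_k x(n-k) + e(n)
## and the final prediction-error variance.
levinsonDurbin <- function(cv, p) {
  a <- numeric(0)
  sig <- cv[1L]
  for (m in seq_len(p)) {
    if (sig <= 0) stop("prediction-error variance collapsed to zero at order ", m - 1L)
    k <- (cv[m + 1L] - if (m > 1L) sum(a * cv[m:2L]) else 0) / sig
    aNew <- c(a - k * rev(a), k)
    a <- aNew
    sig <- sig * (1 - k^2)
  }
  list(coefficients = a, noiseVariance = sig)
}

#' Fit an autoregressive model by the Yule-Walker method
#'
#' Solves the Yule-Walker equations on the biased sample autocovariance via
#' the Levinson-Durbin recursion. Coefficients follow the generative
#' convention `x(n) = sum_k a_k x(n-k) + e(n)`; the prediction-error
#' (innovation) variance is the recursion's final error variance.
#'
#' @param x numeric vector (demeaned internally).
#' @param p model order (default 10, the conventional choice for EEG).
#' @param demean subtract the sample mean first (default TRUE).
#' @return A list of class `"arModel"` with `order`, `coefficients`
#'   (length `p`) and `noiseVariance`.
#' @examples
#' x <- simulateAR(c(0.5, -0.25), 5000, seed = 1)
#' fitARYuleWalker(x, p = 2)
#' @export
fitARYuleWalker <- function(x, p = 10, demean = TRUE) {
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be a positive integer")
  if (length(x) <= p) {
    stop(sprintf("need more than p = %d samples, got %d", p, length(x)))
  }
  if (demean) x <- x - mean(x)
  if (all(abs(x) < .Machine$double.eps * 10)) {
    stop("input is constant; AR model is undefined")
  }
  cv <- biasedAutocov(x, p)
  fit <- levinsonDurbin(cv, p)
  structure(
    list(order = p, coefficients = fit$coefficients,
         noiseVariance = fit$noiseVariance),
    class = "arModel"
  )
}

#' Evaluate the parametric AR spectrum
#'
#' The power spectral density implied by an AR(p) model,
#' `S(f) = sigma^2 / (fs * |1 - sum_k a_k exp(-i 2 pi f k / fs)|^2)`,
#' with coefficients in the generative convention. This is both the
#' estimator's evaluation step and the closed-form oracle for a known model.
#'
#' @param model an `"arModel"` (or a list with `coefficients` and
#'   `noiseVariance`).
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of non-negative power values, one per frequency.
#' @export
arSpectrum <- function(model, freqs, fs) {
  a <- model$coefficients
  k <- seq_along(a)
  E <- exp(-2i * pi * outer(freqs, k) / fs) # nFreq x p
  denom <- abs(1 - as.vector(E %*% a))^2
  as.numeric(model$noiseVariance / (fs * denom))
}

#' Simulate a stationary AR process
#'
#' @param a AR coefficients in the generative convention.
#' @param n number of samples returned.
#' @param sd innovation standard deviation.
#' @param burnin samples discarded from the start.
#' @param seed optional RNG seed.
#' @return Numeric vector of length `n`.
#' @export
simulateAR <- function(a, n, sd = 1, burnin = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n + burnin, sd = sd)
  x <- stats::filter(e, a, method = "recursive")
  as.numeric(x[(burnin + 1L):(burnin + n)])
}

hammingWindow <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

## AR spectra for many windows at once: coef matrix (nWin x p), sig2 vector.
## Returns nWin x nFreq power matrix.
arSpectrumMatrix <- function(coefs, sig2, freqs, fs) {
  p <- ncol(coefs)
  E <- exp(-2i * pi * outer(seq_len(p), freqs) / fs) # p x nFreq
  D <- 1 - coefs %*% E
  sweep(1 / abs(D)^2, 1L, sig2 / fs, `*`)
}

#' Sliding-window Yule-Walker AR power spectral density
#'
#' Estimates the PSD of one signal by fitting an AR(p) model in sliding
#' Hamming-tapered windows (default 250 samples, half overlapping) and
#' averaging the per-window parametric spectra on a fixed frequency grid.
#' Each window is demeaned, tapered and its autocovariance rescaled by the
#' taper's power (`mean(w^2)`) so the absolute power scale is preserved.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param p AR order (default 10).
#' @param windowSamples sliding-window length (default 250).
#' @param overlap fractional overlap between consecutive windows
#'   (default 0.5).
#' @param freqStep frequency-grid spacing in Hz (default 0.5).
#' @details The signal is demeaned once, globally. Demeaning every short
#'   window separately would act as a high-pass filter at roughly the
#'   reciprocal window length (4 Hz for 250 samples at 1000 Hz) and destroy
#'   the delta band.
#' @return A list of class `"psdEstimate"`: `freqs`, `power` (non-negative),
#'   `nWindows`, plus the method parameters.
#' @examples
#' x <- simulateAR(c(0.5, -0.25), 4000, seed = 1)
#' est <- psdAR(x, fs = 500)
#' head(est$freqs)
#' @export
psdAR <- function(x, fs, p = 10, windowSamples = 250, overlap = 0.5,
                  freqStep = 0.5) {
  if (windowSamples <= p) stop("'windowSamples' must exceed the AR order")
  n <- length(x)
  if (n < windowSamples) {
    stop(sprintf("signal (%d samples) shorter than one window (%d)",
                 n, windowSamples))
  }
  x <- x - mean(x)
  step <- max(1L, as.integer(round(windowSamples * (1 - overlap))))
  starts <- seq(1L, n - windowSamples + 1L, by = step)
  w <- hammingWindow(windowSamples)
  w2 <- mean(w^2)
  idx <- outer(seq_len(windowSamples) - 1L, starts, `+`) # win x nWin
  W <- matrix(x[idx], nrow = windowSamples) * w
  # autocovariances for all windows at once, corrected for taper power
  cv <- matrix(NA_real_, length(starts), p + 1L)
  for (k in 0:p) {
    cv[, k + 1L] <- colSums(W[seq_len(windowSamples - k), , drop = FALSE] *
                            W[(k + 1L):windowSamples, , drop = FALSE]) /
                    (windowSamples * w2)
  }
  coefs <- matrix(NA_real_, length(starts), p)
  sig2 <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fit <- levinsonDurbin(cv[i, ], p)
    coefs[i, ] <- fit$coefficients
    sig2[i] <- fit$noiseVariance
  }
  freqs <- seq(0, fs / 2, by = freqStep)
  power <- colMeans(arSpectrumMatrix(coefs, sig2, freqs, fs))
  structure(
    list(freqs = freqs, power = power, nWindows = length(starts),
         order = p, windowSamples = windowSamples, overlap = overlap,
         fs = fs),
    class = "psdEstimate"
  )
}

#' @export
print.psdEstimate <- function(x, ...) {
  cat(sprintf(
    "AR(%d) PSD estimate: %d frequencies in [0, %g] Hz, %d window(s)\n",
    x$order, length(x$freqs), max(x$freqs), x$nWindows
  ))
  invisible(x)
}

#' Per-epoch, per-channel AR PSD of an EpochSet
#'
#' @param eps an [EpochSet-class].
#' @inheritParams psdAR
#' @return A list with `freqs` and `power`, a 3-d array
#'   (epoch x channel x frequency).
#' @export
psdAREpochs <- function(eps, p = 10, windowSamples = 250, overlap = 0.5,
                        freqStep = 0.5) {
  d <- dim(eps@epochs)
  freqs <- seq(0, eps@fs / 2, by = freqStep)
  power <- array(NA_real_, c(d[1L], d[2L], length(freqs)))
  for (e in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      power[e, ch, ] <- psdAR(eps@epochs[e, ch, ], eps@fs, p = p,
                              windowSamples = windowSamples,
                              overlap = overlap, freqStep = freqStep)$power
    }
  }
  list(freqs = freqs, power = power)
}

## Trapezoidal integral of (freqs, power) over [lo, hi], with linear
## interpolation at the interval end points.
trapezoidBandPower <- function(freqs, power, lo, hi) {
  if (lo >= hi) stop("empty frequency interval")
  inside <- freqs > lo & freqs < hi
  fpts <- c(lo, freqs[inside], hi)
  ppts <- c(
    stats::approx(freqs, power, xout = lo, rule = 2)$y,
    power[inside],
    stats::approx(freqs, power, xout = hi, rule = 2)$y
  )
  sum(diff(fpts) * (ppts[-1L] + ppts[-length(ppts)])) / 2
}

#' Relative band power of a PSD estimate
#'
#' Fraction of total power in `[fLow, fHigh)` relative to the full analysis
#' range (default 0.5-100 Hz), computed by trapezoidal integration on the
#' PSD's frequency grid.
#'
#' @param psd a `"psdEstimate"` (or list with `freqs` and `power`).
#' @param fLow,fHigh band edges in Hz; either explicit or via `band`.
#' @param band a band name from [eegBands()].
#' @param totalRange length-2 numeric, the denominator range in Hz.
#' @return A single value in [0, 1].
#' @export
relativeBandPower <- function(psd, fLow = NULL, fHigh = NULL, band = NULL,
                              totalRange = c(0.5, 100)) {
  if (!is.null(band)) {
    bt <- eegBands()
    i <- match(band, bt$band)
    if (is.na(i)) stop("unknown band name: ", band)
    fLow <- bt$low[i]; fHigh <- bt$high[i]
  }
  if (is.null(fLow) || is.null(fHigh)) {
    stop("either 'band' or both 'fLow' and 'fHigh' must be given")
  }
  if (fLow < totalRange[1L] - 1e-9 || fHigh > totalRange[2L] + 1e-9) {
    stop(sprintf("band [%g, %g) lies outside the total range [%g, %g]",
                 fLow, fHigh, totalRange[1L], totalRange[2L]))
  }
  if (totalRange[2L] > max(psd$freqs) + 1e-9) {
    stop("total range exceeds the PSD's frequency support")
  }
  num <- trapezoidBandPower(psd$freqs, psd$power, fLow, fHigh)
  den <- trapezoidBandPower(psd$freqs, psd$power, totalRange[1L], totalRange[2L])
  num / den
}

#' Relative band powers for every epoch and channel
#'
#' Runs [psdAREpochs()] and integrates the six sub-bands of [eegBands()]
#' (or a custom band table) for every epoch x channel.
#'
#' @param eps an [EpochSet-class].
#' @param bands band table as from [eegBands()].
#' @inheritParams psdAR
#' @param totalRange denominator range in Hz.
#' @return A data.frame: `subject`, `label`, `epoch`, `channel`, `band`,
#'   `rpsd`.
#' @export
spectralFeatures <- function(eps, bands = eegBands(), p = 10,
                             windowSamples = 250, overlap = 0.5,
                             freqStep = 0.5, totalRange = c(0.5, 100)) {
  est <- psdAREpochs(eps, p = p, windowSamples = windowSamples,
                     overlap = overlap, freqStep = freqStep)
  d <- dim(est$power)
  rows <- vector("list", d[1L] * d[2L])
  ri <- 0L
  for (e in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      one <- list(freqs = est$freqs, power = est$power[e, ch, ])
      vals <- vapply(seq_len(nrow(bands)), function(b) {
        relativeBandPower(one, bands$low[b], bands$high[b],
                          totalRange = totalRange)
      }, numeric(1))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subject = eps@subjectId, label = eps@label, epoch = e,
        channel = eps@channelLabels[ch], band = bands$band,
        rpsd = vals, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw` from the classical symmetric tridiagonal eigenproblem.
#' Tapers are unit-energy and mutually orthogonal.
#'
#' @param n taper length in samples.
#' @param k number of tapers.
#' @param nw time-bandwidth product (default 2).
#' @return An `n x k` matrix, one taper per column.
#' @export
dpssTapers <- function(n, k, nw = 2) {
  if (k < 1L || k >= n) stop("'k' must be in [1, n)")
  W <- nw / n
  t0 <- seq_len(n) - 1
  diag0 <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  M <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(off, diag0, off), symmetric = FALSE)
  es <- RSpectra::eigs_sym(M, k = k, which = "LA")
  V <- es$vectors[, order(es$values, decreasing = TRUE), drop = FALSE]
  # normalise and fix sign (positive mean for symmetric tapers, positive
  # initial slope otherwise)
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) v <- -v
    } else if (v[2L] - v[1L] < 0) {
      v <- -v
    }
    V[, j] <- v
  }
  V
}

#' Multitaper time-varying AR spectrum
#'
#' Sliding-window time-frequency analysis in which each window is tapered
#' with `k` orthogonal Slepian sequences, each tapered copy is fitted with a
#' Yule-Walker AR(p) model, and the `k` parametric spectra are averaged,
#' reducing estimator variance. `k = 1` degenerates to a single-taper
#' sliding-window AR spectrogram.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param k number of tapers (default 3).
#' @param nw time-bandwidth product of the tapers (default 2).
#' @param windowSizeS window length in seconds (default 2).
#' @param windowStepS window step in seconds (default 0.1).
#' @param p AR order (default 10).
#' @param freqStep frequency-grid spacing in Hz.
#' @return A list of class `"tvSpectrum"`: `times` (window centres, s),
#'   `freqs` (Hz), `power` (time x frequency, non-negative), and the method
#'   parameters.
#' @export
multitaperSpectrogram <- function(x, fs, k = 3, nw = 2, windowSizeS = 2,
                                  windowStepS = 0.1, p = 10, freqStep = 0.5) {
  win <- as.integer(round(windowSizeS * fs))
  step <- max(1L, as.integer(round(windowStepS * fs)))
  if (k < 1L) stop("'k' must be >= 1")
  if (win <= p) stop("window must contain more samples than the AR order")
  if (length(x) < win) stop("signal shorter than one window")
  tapers <- dpssTapers(win, k, nw)
  tp2 <- colMeans(tapers^2)
  starts <- seq(1L, length(x) - win + 1L, by = step)
  freqs <- seq(0, fs / 2, by = freqStep)
  power <- matrix(NA_real_, length(starts), length(freqs))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1L)]
    seg <- seg - mean(seg)
    acc <- numeric(length(freqs))
    for (j in seq_len(k)) {
      y <- seg * tapers[, j]
      cv <- biasedAutocov(y, p) / tp2[j]
      fit <- levinsonDurbin(cv, p)
      acc <- acc + arSpectrum(fit, freqs, fs)
    }
    power[i, ] <- acc / k
  }
  structure(
    list(times = (starts - 1L + win / 2) / fs, freqs = freqs, power = power,
         k = k, nw = nw, windowSizeS = windowSizeS, windowStepS = windowStepS,
         order = p, fs = fs),
    class = "tvSpectrum"
  )
}

#' @export
print.tvSpectrum <- function(x, ...) {
  cat(sprintf(
    "Multitaper AR(%d) spectrogram: %d windows x %d frequencies, K = %d tapers\n",
    x$order, length(x$times), length(x$freqs), x$k
  ))
  invisible(x)
}

#' Band power trajectory of a time-varying spectrum
#'
#' Integrates a `"tvSpectrum"` over one band per time window (trapezoidal
#' rule), yielding the band-power time course used for state monitoring.
#'
#' @param tv a `"tvSpectrum"` from [multitaperSpectrogram()].
#' @param fLow,fHigh band edges in Hz; either explicit or via `band`.
#' @param band a band name from [eegBands()].
#' @return A data.frame with `time` (s) and `power`.
#' @export
bandPowerTimecourse <- function(tv, fLow = NULL, fHigh = NULL, band = NULL) {
  if (!is.null(band)) {
    bt <- eegBands()
    i <- match(band, bt$band)
    if (is.na(i)) stop("unknown band name: ", band)
    fLow <- bt$low[i]; fHigh <- bt$high[i]
  }
  pw <- apply(tv$power, 1L, function(pr) {
    trapezoidBandPower(tv$freqs, pr, fLow, fHigh)
  })
  data.frame(time = tv$times, power = pw)
}
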