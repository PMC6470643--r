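#' Specify a synthetic two-class EEG cohort
#'
#' Builds and validates a [SynthCohortSpec-class]. The two classes emulate
#' the qualitative signatures of the clinical groups: a delta-dominant,
#' low-diversity "coma-like" class (label 0) and a spectrally flatter,
#' high-diversity "death-like" class (label 1). Each subject's signal is a
#' sum of band-limited stochastic components whose expected band powers
#' follow the class profile, mixed with a class-specific fraction of
#' broadband white noise that controls ordinal pattern diversity.
#'
#' @param nSubjectsPerClass subjects per class.
#' @param nChannels channels per subject (default 6, a frontal montage).
#' @param fs sampling rate in Hz (default 1000).
#' @param epochSeconds epoch length in seconds (default 60).
#' @param epochsPerSubject epochs per subject (default 5).
#' @param classProfiles 2 x 6 matrix of band-power weights over
#'   (delta, theta, alpha, beta, gamma1, gamma2); rows sum to 1. The default
#'   gives class 0 a delta weight of 0.85 and class 1 a flatter profile with
#'   delta weight 0.60.
#' @param classNoiseFraction per-class broadband-noise fraction in [0, 1]
#'   (default 0.1 and 0.6).
#' @param subjectWeightSd lognormal sd of per-subject band-weight jitter
#'   (default 0.15).
#' @param subjectNoiseSd logit-scale sd of per-subject noise-fraction jitter
#'   (default 0.25).
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   cohorts.
#' @return A validated [SynthCohortSpec-class].
#' @examples
#' spec <- synthCohortSpec(2, fs = 250, epochSeconds = 4, seed = 1)
#' cohort <- generateCohort(spec)
#' cohort[[1]]
#' @export
synthCohortSpec <- function(nSubjectsPerClass,
                            nChannels = 6,
                            fs = 1000,
                            epochSeconds = 60,
                            epochsPerSubject = 5,
                            classProfiles = defaultClassProfiles(),
                            classNoiseFraction = c(0.1, 0.6),
                            subjectWeightSd = 0.15,
                            subjectNoiseSd = 0.25,
                            seed = 1L) {
  new("SynthCohortSpec",
    nSubjectsPerClass = as.integer(nSubjectsPerClass),
    nChannels = as.integer(nChannels),
    fs = as.numeric(fs),
    epochSeconds = as.numeric(epochSeconds),
    epochsPerSubject = as.integer(epochsPerSubject),
    classProfiles = classProfiles,
    classNoiseFraction = as.numeric(classNoiseFraction),
    subjectWeightSd = as.numeric(subjectWeightSd),
    subjectNoiseSd = as.numeric(subjectNoiseSd),
    seed = as.integer(seed)
  )
}

#' Default class band-power profiles
#'
#' Class 0 (coma-like) is strongly delta-dominant; class 1 (death-like)
#' spreads relatively more power into the faster bands, mirroring the
#' reported direction of the clinical contrast (delta power decreased,
#' alpha/beta increased in the death-like group).
#'
#' @return A 2 x 6 matrix of band weights, rows summing to 1.
#' @export
defaultClassProfiles <- function() {
  m <- rbind(
    comaLike  = c(0.85, 0.06, 0.04, 0.03, 0.012, 0.008),
    deathLike = c(0.60, 0.12, 0.10, 0.08, 0.050, 0.050)
  )
  colnames(m) <- eegBands()$band
  m
}

## One channel-epoch synthesised in the frequency domain: a complex-Gaussian
## spectrum shaped so the expected power in band b is (1 - q) * w_b and the
## remaining fraction q is broadband (flat over (0, fs/2)). Distributionally
## identical to summing band-pass-filtered white noise components.
synthChannelEpoch <- function(n, fs, weights, q, bands) {
  df <- fs / n
  nh <- n %/% 2 # positive-frequency bins 1..nh (excluding DC)
  f <- (1:nh) * df
  shape <- rep(q / (fs / 2), nh) # broadband floor (per Hz)
  for (b in seq_len(nrow(bands))) {
    inb <- f >= bands$low[b] & f < bands$high[b]
    if (any(inb)) {
      width <- sum(inb) * df
      shape[inb] <- shape[inb] + (1 - q) * weights[b] / width
    }
  }
  # complex gaussian spectrum with E|Z_k|^2 = shape_k * df * n^2 / 2 per
  # side, so that the reconstructed real signal has the target band powers
  amp <- sqrt(shape * df / 2) * n
  z <- complex(
    real = rnorm(nh, sd = sqrt(0.5)),
    imaginary = rnorm(nh, sd = sqrt(0.5))
  ) * amp
  spec <- complex(real = numeric(n))
  spec[2:(nh + 1L)] <- z
  # Hermitian symmetry; Nyquist bin (even n) forced real
  if (n %% 2L == 0L) {
    spec[nh + 1L] <- complex(real = sqrt(2) * Re(z[nh]))
    if (nh > 1L) spec[n:(n - nh + 2L)] <- Conj(z[1:(nh - 1L)])
  } else {
    spec[n:(n - nh + 1L)] <- Conj(z)
  }
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate a labelled synthetic two-class cohort
#'
#' Produces one [EEGRecording-class] per subject (class 0 = coma-like,
#' class 1 = death-like), each `epochsPerSubject * epochSeconds` seconds
#' long so that [segmentEpochs()] recovers the stated epoch structure.
#' Band weights and noise fraction are jittered per subject (lognormal /
#' logit-normal) to create between-subject variability; identical specs
#' (including the seed) generate bit-identical cohorts.
#'
#' @param spec a [SynthCohortSpec-class] from [synthCohortSpec()].
#' @return A list of [EEGRecording-class] objects with class labels, in
#'   class-0-then-class-1 order.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  bands <- eegBands()
  spe <- as.integer(round(spec@epochSeconds * spec@fs))
  nTot <- spe * spec@epochsPerSubject
  labels <- rep(0:1, each = spec@nSubjectsPerClass)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cls <- labels[i] + 1L
    w <- spec@classProfiles[cls, ] *
      exp(rnorm(6L, sd = spec@subjectWeightSd))
    w <- w / sum(w)
    q0 <- min(max(spec@classNoiseFraction[cls], 1e-6), 1 - 1e-6)
    q <- stats::plogis(stats::qlogis(q0) + rnorm(1L, sd = spec@subjectNoiseSd))
    dat <- matrix(NA_real_, spec@nChannels, nTot)
    for (ch in seq_len(spec@nChannels)) {
      for (e in seq_len(spec@epochsPerSubject)) {
        dat[ch, ((e - 1L) * spe + 1L):(e * spe)] <-
          synthChannelEpoch(spe, spec@fs, w, q, bands)
      }
    }
    out[[i]] <- EEGRecording(
      data = dat, fs = spec@fs,
      channelLabels = defaultChannelLabels(spec@nChannels),
      subjectId = sprintf("class%d_s%02d", labels[i],
                          ((i - 1L) %% spec@nSubjectsPerClass) + 1L),
      label = labels[i]
    )
  }
  out
}

defaultChannelLabels <- function(n) {
  frontal <- c("FP1", "FP2", "F3", "F4", "F7", "F8")
  if (n <= 6L) frontal[seq_len(n)] else c(frontal, paste0("ch", 7:n))
}

#' Generate a two-state change-point recording
#'
#' Single-subject monitoring scenario: the first half of the recording
#' follows one class profile, the second half the other, switching at the
#' midpoint. Used to exercise time-varying band power and time-varying
#' permutation entropy.
#'
#' @param spec a [SynthCohortSpec-class]; profiles/noise of class 0 are used
#'   for the first half and of class 1 for the second.
#' @param totalSeconds total duration in seconds.
#' @return An [EEGRecording-class] with one channel per `spec@nChannels`.
#' @export
generateStateSwitch <- function(spec, totalSeconds = 60) {
  validObject(spec)
  set.seed(spec@seed)
  bands <- eegBands()
  nHalf <- as.integer(round(totalSeconds * spec@fs / 2))
  dat <- matrix(NA_real_, spec@nChannels, 2L * nHalf)
  for (ch in seq_len(spec@nChannels)) {
    q1 <- min(max(spec@classNoiseFraction[1L], 1e-6), 1 - 1e-6)
    q2 <- min(max(spec@classNoiseFraction[2L], 1e-6), 1 - 1e-6)
    dat[ch, seq_len(nHalf)] <-
      synthChannelEpoch(nHalf, spec@fs, spec@classProfiles[1L, ], q1, bands)
    dat[ch, (nHalf + 1L):(2L * nHalf)] <-
      synthChannelEpoch(nHalf, spec@fs, spec@classProfiles[2L, ], q2, bands)
  }
  EEGRecording(
    data = dat, fs = spec@fs,
    channelLabels = defaultChannelLabels(spec@nChannels),
    subjectId = "stateSwitch", label = NA
  )
}
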