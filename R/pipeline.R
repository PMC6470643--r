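#' Run the full discrimination pipeline on a labelled cohort
#'
#' End-to-end orchestration: segment each recording into non-overlapping
#' epochs; estimate per-epoch, per-channel AR spectra and delta-band
#' relative power; compute per-epoch, per-channel permutation entropy;
#' epoch-average both into subjects x electrodes views; run per-feature
#' group ANOVA with Bonferroni correction; assemble the four feature sets
#' (PCA-reduced spectral view, PCA-reduced complexity view, their
#' concatenation, and the CCA-fused features); and evaluate each with a
#' leave-one-out Gaussian-kernel SVM with nested grid search.
#'
#' @param recordings list of labelled [EEGRecording-class] objects.
#' @param epochSeconds epoch length in seconds (default 60).
#' @param nEpochs epochs per subject (default NULL: as many as fit).
#' @param band sub-band used for the spectral view (default `"delta"`).
#' @param p AR model order (default 10).
#' @param windowSamples AR sliding-window length (default 250).
#' @param m,tau permutation-entropy order and lag (defaults 4, 1).
#' @param varianceThreshold PCA explained-variance rule (default 0.70).
#' @param alpha significance level for the group statistics (default 0.01).
#' @param innerFolds,seed,stages SVM evaluation settings
#'   (see [evaluateLOOCV()]).
#' @param classify run the SVM stage (default TRUE); with FALSE the
#'   function stops after features, statistics and fusion.
#' @return A list: `rpsdView`, `peView` (subjects x electrodes matrices),
#'   `labels`, `rpsdStats`, `peStats` (ANOVA tables), `sets`
#'   (from [assembleFeatureSets()]), and — when `classify` — `reports` and
#'   `summary` (from [compareFeatureSets()]).
#' @export
runPipeline <- function(recordings, epochSeconds = 60, nEpochs = NULL,
                        band = "delta", p = 10, windowSamples = 250,
                        m = 4, tau = 1, varianceThreshold = 0.70,
                        alpha = 0.01, innerFolds = 3, seed = 1, stages = 3,
                        classify = TRUE) {
  labels <- vapply(recordings, subjectLabel, integer(1))
  if (anyNA(labels)) stop("all recordings must carry a class label")
  spectral <- vector("list", length(recordings))
  complexity <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    eps <- segmentEpochs(recordings[[i]], epochSeconds, nEpochs)
    spectral[[i]] <- spectralFeatures(eps, p = p,
                                      windowSamples = windowSamples)
    complexity[[i]] <- complexityFeatures(eps, m = m, tau = tau)
  }
  spectral <- do.call(rbind, spectral)
  complexity <- do.call(rbind, complexity)
  rv <- featureView(spectral, "rpsd", band = band)
  pv <- featureView(complexity, "pe")
  stopifnot(identical(rownames(rv$view), rownames(pv$view)))
  out <- list(
    rpsdView = rv$view, peView = pv$view, labels = rv$labels,
    spectralFeatures = spectral, complexityFeatures = complexity,
    rpsdStats = groupStats(rv$view, rv$labels, alpha = alpha),
    peStats = groupStats(pv$view, pv$labels, alpha = alpha),
    sets = assembleFeatureSets(rv$view, pv$view,
                               varianceThreshold = varianceThreshold)
  )
  if (classify) {
    cmp <- compareFeatureSets(
      out$sets[c("set1", "set2", "set3", "set4")], rv$labels,
      innerFolds = innerFolds, seed = seed, stages = stages
    )
    out$reports <- cmp$reports
    out$summary <- cmp$summary
  }
  out
}
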