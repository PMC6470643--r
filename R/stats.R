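#' One-way two-group ANOVA
#'
#' Standard one-way ANOVA F statistic for two groups, with (1, n1 + n2 - 2)
#' degrees of freedom. For two groups the F value equals the square of the
#' pooled two-sample t statistic.
#'
#' @param group1,group2 numeric vectors of per-subject feature values.
#' @return A list with `fValue`, `pValue` and `df` (numerator, denominator).
#' @examples
#' anovaOneway(c(1, 2, 3), c(4, 5, 7))
#' @export
anovaOneway <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  ssw <- sum((group1 - mean(group1))^2) + sum((group2 - mean(group2))^2)
  if (ssw <= 0) stop("zero within-group variance; F is undefined")
  gm <- mean(c(group1, group2))
  ssb <- n1 * (mean(group1) - gm)^2 + n2 * (mean(group2) - gm)^2
  df2 <- n1 + n2 - 2L
  f <- (ssb / 1) / (ssw / df2)
  list(fValue = f, pValue = pf(f, 1, df2, lower.tail = FALSE),
       df = c(1L, df2))
}

#' Bonferroni correction for a family of tests
#'
#' @param pValues raw p-values in [0, 1].
#' @param alpha familywise significance level (default 0.01).
#' @param k family size; defaults to `length(pValues)` (typically 6: one
#'   test per band or per electrode).
#' @return A data.frame with `p`, `pCorrected` (`min(1, p * k)`),
#'   `nComparisons` and `significant` at `alpha`.
#' @export
bonferroniCorrect <- function(pValues, alpha = 0.01, k = length(pValues)) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  pc <- pmin(1, pValues * k)
  data.frame(
    p = pValues, pCorrected = pc, nComparisons = k,
    significant = pc < alpha
  )
}

#' Group statistics for a subjects x features view
#'
#' Per-feature one-way ANOVA between the two classes, with Bonferroni
#' correction across the feature family. The unit of observation is the
#' subject (features are expected to be epoch-averaged beforehand to avoid
#' pseudo-replication).
#'
#' @param view numeric matrix, subjects x features, with column names.
#' @param labels class labels (0/1), one per row of `view`.
#' @param alpha familywise significance level (default 0.01).
#' @param k family size for the correction; default `ncol(view)`.
#' @return A data.frame with one row per feature: `feature`, `fValue`, `p`,
#'   `pCorrected`, `significant`.
#' @export
groupStats <- function(view, labels, alpha = 0.01, k = ncol(view)) {
  view <- as.matrix(view)
  if (nrow(view) != length(labels)) stop("one label per row is required")
  res <- lapply(seq_len(ncol(view)), function(j) {
    a <- anovaOneway(view[labels == 0, j], view[labels == 1, j])
    data.frame(
      feature = if (is.null(colnames(view))) paste0("f", j) else colnames(view)[j],
      fValue = a$fValue, p = a$pValue, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  corr <- bonferroniCorrect(res$p, alpha = alpha, k = k)
  res$pCorrected <- corr$pCorrected
  res$significant <- corr$significant
  res
}

#' Epoch-averaged subject x channel feature view
#'
#' Collapses a long per-epoch feature table (as returned by
#' [spectralFeatures()] or [complexityFeatures()]) into a subjects x
#' channels matrix by averaging over epochs, the unit used for group
#' statistics and classification.
#'
#' @param features long data.frame with columns `subject`, `label`,
#'   `channel`, the value column, and optionally `band`.
#' @param value name of the value column (`"rpsd"` or `"pe"`).
#' @param band optional band name to filter on (for banded tables).
#' @return A list with `view` (subjects x channels matrix, rownames =
#'   subject ids) and `labels` (0/1 per subject).
#' @export
featureView <- function(features, value = c("rpsd", "pe"), band = NULL) {
  value <- match.arg(value)
  if (!is.null(band)) {
    if (!"band" %in% names(features)) stop("feature table has no 'band' column")
    features <- features[features$band == band, , drop = FALSE]
    if (!nrow(features)) stop("no rows for band '", band, "'")
  }
  subjects <- unique(features$subject)
  channels <- unique(features$channel)
  agg <- stats::aggregate(
    features[[value]],
    by = list(subject = features$subject, channel = features$channel),
    FUN = mean
  )
  view <- matrix(NA_real_, length(subjects), length(channels),
                 dimnames = list(subjects, channels))
  view[cbind(match(agg$subject, subjects), match(agg$channel, channels))] <- agg$x
  labels <- features$label[match(subjects, features$subject)]
  list(view = view, labels = as.integer(labels))
}
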