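#' PCA reduction with an explained-variance rule
#'
#' Column-centers (and by default z-scores) a subjects x features view and
#' retains the minimal number of leading principal components whose
#' cumulative explained-variance fraction reaches `varianceThreshold`
#' (default 0.70).
#'
#' @param view numeric matrix, subjects x features (no missing values).
#' @param varianceThreshold cumulative explained-variance fraction to reach.
#' @param scale z-score columns before PCA (default TRUE; sensible when the
#'   views mix unit-free ratios with entropies in nats).
#' @return A list of class `"pcaReduction"`: `scores` (subjects x k),
#'   `loadings`, `explained` (per-component fractions), `nComponents`,
#'   `center`, `scale`.
#' @examples
#' v <- matrix(rnorm(60), 10, 6)
#' pcaReduce(v)$nComponents
#' @export
pcaReduce <- function(view, varianceThreshold = 0.70, scale = TRUE) {
  view <- as.matrix(view)
  if (anyNA(view)) stop("'view' contains missing values")
  if (nrow(view) < 2L) stop("PCA needs at least 2 subjects")
  sds <- apply(view, 2L, sd)
  if (all(sds < .Machine$double.eps * 100)) {
    stop("all features are constant; PCA is undefined")
  }
  scl <- NULL
  if (scale) {
    scl <- ifelse(sds < .Machine$double.eps * 100, 1, sds)
    view <- sweep(view, 2L, scl, `/`)
  }
  pc <- prcomp(view, center = TRUE, scale. = FALSE)
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_along(pc$sdev)) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= varianceThreshold - 1e-12)[1L]
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explained = ev, nComponents = k,
      center = pc$center, scale = scl,
      varianceThreshold = varianceThreshold
    ),
    class = "pcaReduction"
  )
}

#' @export
print.pcaReduction <- function(x, ...) {
  cat(sprintf(
    "PCA reduction: %d component(s) retained (cumulative variance %.1f%% >= %.0f%%)\n",
    x$nComponents, 100 * sum(x$explained[seq_len(x$nComponents)]),
    100 * x$varianceThreshold
  ))
  invisible(x)
}

## numeric rank from singular values, tolerance max(dim) * eps * sigma_max
svdRank <- function(d, dims) {
  tol <- max(dims) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

#' Canonical correlation feature fusion (compact-SVD construction)
#'
#' Fuses two column-centred feature views A and B by the three-step SVD
#' construction: compact SVDs `A = U_A S_A V_A'` and `B = U_B S_B V_B'`;
#' SVD of the cross-product `U_A' U_B = U S V'`, whose singular values are
#' the canonical correlations; projection matrices `W_A = V_A S_A^{-1} U`
#' and `W_B = V_B S_B^{-1} V`. The fused matrix `Z = [A W_A | B W_B]` has
#' `2 r` columns with `r = min(rank(A), rank(B))` — the canonical
#' correlation discriminative features.
#'
#' @param A,B numeric matrices with one row per subject (equal row counts).
#'   Columns are centred internally.
#' @return A [CCAFusion-class].
#' @examples
#' A <- matrix(rnorm(40), 20, 2); B <- matrix(rnorm(40), 20, 2)
#' ccaFuse(A, B)
#' @export
ccaFuse <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    stop(sprintf("subject counts differ: %d vs %d", nrow(A), nrow(B)))
  }
  if (nrow(A) < 2L) stop("CCA needs at least 2 subjects")
  cA <- colMeans(A); cB <- colMeans(B)
  A <- sweep(A, 2L, cA); B <- sweep(B, 2L, cB)
  sa <- svd(A); sb <- svd(B)
  ra <- svdRank(sa$d, dim(A)); rb <- svdRank(sb$d, dim(B))
  if (ra < 1L || rb < 1L) stop("zero-rank view; CCA is undefined")
  UA <- sa$u[, seq_len(ra), drop = FALSE]
  VA <- sa$v[, seq_len(ra), drop = FALSE]
  dA <- sa$d[seq_len(ra)]
  UB <- sb$u[, seq_len(rb), drop = FALSE]
  VB <- sb$v[, seq_len(rb), drop = FALSE]
  dB <- sb$d[seq_len(rb)]
  cs <- svd(crossprod(UA, UB))
  r <- min(ra, rb)
  U <- cs$u[, seq_len(r), drop = FALSE]
  V <- cs$v[, seq_len(r), drop = FALSE]
  rho <- pmin(pmax(cs$d[seq_len(r)], 0), 1)
  WA <- VA %*% (U / dA)
  WB <- VB %*% (V / dB)
  # deterministic paired sign convention (flipping a u/v pair together
  # leaves the canonical correlations unchanged)
  for (j in seq_len(r)) {
    if (WA[which.max(abs(WA[, j])), j] < 0) {
      WA[, j] <- -WA[, j]
      WB[, j] <- -WB[, j]
    }
  }
  X <- A %*% WA
  Y <- B %*% WB
  new("CCAFusion",
    X = X, Y = Y, Z = cbind(X, Y), WA = WA, WB = WB,
    correlations = rho, centerA = cA, centerB = cB
  )
}

#' Canonical correlations accessor
#'
#' @param object a [CCAFusion-class].
#' @return Numeric vector of canonical correlations (non-increasing).
#' @export
setGeneric("canonicalCorrelations",
           function(object) standardGeneric("canonicalCorrelations"))

#' @rdname canonicalCorrelations
#' @export
setMethod("canonicalCorrelations", "CCAFusion",
          function(object) object@correlations)

#' Fused feature matrix accessor
#'
#' @param object a [CCAFusion-class].
#' @return The subjects x 2r fused matrix `Z`.
#' @export
setGeneric("fusedFeatures", function(object) standardGeneric("fusedFeatures"))

#' @rdname fusedFeatures
#' @export
setMethod("fusedFeatures", "CCAFusion", function(object) object@Z)

#' Assemble the four classification feature sets
#'
#' From a spectral view (per-electrode delta-band relative power) and a
#' complexity view (per-electrode permutation entropy), builds the four
#' feature sets compared in the study design: set1 = PCA-reduced spectral
#' view, set2 = PCA-reduced complexity view, set3 = their column
#' concatenation, set4 = the CCA-fused features from set1 and set2.
#'
#' @param rpsdView subjects x electrodes matrix of relative band powers.
#' @param peView subjects x electrodes matrix of permutation entropies
#'   (same subjects, same order).
#' @param varianceThreshold PCA explained-variance rule (default 0.70).
#' @param scale z-score each view before PCA (default TRUE).
#' @return A list with elements `set1`..`set4` (matrices), `pcaRpsd`,
#'   `pcaPe` (the `"pcaReduction"` objects) and `fusion`
#'   (the [CCAFusion-class]).
#' @export
assembleFeatureSets <- function(rpsdView, peView, varianceThreshold = 0.70,
                                scale = TRUE) {
  rpsdView <- as.matrix(rpsdView); peView <- as.matrix(peView)
  if (nrow(rpsdView) != nrow(peView)) {
    stop("the two views must share subjects (row counts differ)")
  }
  if (nrow(rpsdView) < 2L) stop("need at least 2 subjects")
  pa <- pcaReduce(rpsdView, varianceThreshold, scale)
  pb <- pcaReduce(peView, varianceThreshold, scale)
  fu <- ccaFuse(pa$scores, pb$scores)
  list(
    set1 = pa$scores,
    set2 = pb$scores,
    set3 = cbind(pa$scores, pb$scores),
    set4 = fu@Z,
    pcaRpsd = pa, pcaPe = pb, fusion = fu
  )
}
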