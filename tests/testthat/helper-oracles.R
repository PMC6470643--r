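# Independent oracles used across the suite. These deliberately use naive
# algorithms (enumeration, pairwise counting, generalized eigenproblems) so
# they share no code path with the implementations they check.

# Brute-force permutation entropy: enumerate every embedded vector, rank it
# with a stable sort, count patterns, apply the entropy formula.
bruteForcePE <- function(x, m, tau = 1, base = exp(1)) {
  n <- length(x)
  nVec <- n - (m - 1) * tau
  pats <- character(nVec)
  for (i in seq_len(nVec)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = "-") # stable for ties
  }
  pr <- as.numeric(table(pats)) / nVec
  -sum(pr * log(pr)) / log(base)
}

# Naive CCA through the generalized eigenproblem on covariance blocks.
ccaEigenOracle <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  Saa <- crossprod(A); Sbb <- crossprod(B); Sab <- crossprod(A, B)
  M <- solve(Saa, Sab) %*% solve(Sbb, t(Sab))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev, 1), 0))[seq_len(min(ncol(A), ncol(B)))]
}

# O(n^2) pairwise AUC: ties count 1/2.
aucPairwiseOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Two well-separated Gaussian blobs in 2-d.
makeBlobs <- function(nPerClass, separation = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(nPerClass * 2), ncol = 2),
    matrix(rnorm(nPerClass * 2, mean = separation), ncol = 2)
  )
  list(X = X, y = rep(c(0L, 1L), each = nPerClass))
}

# Small helper: a cohort spec scaled for fast tests.
fastCohortSpec <- function(nPerClass, seed, fs = 250, epochSeconds = 4,
                           epochsPerSubject = 2, nChannels = 2, ...) {
  synthCohortSpec(
    nPerClass, nChannels = nChannels, fs = fs, epochSeconds = epochSeconds,
    epochsPerSubject = epochsPerSubject, seed = seed, ...
  )
}
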