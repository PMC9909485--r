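# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# C(n1+n0, n1) group assignments (untied data), doubling the smaller tail.
exactWilcoxonP <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  uAll <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# Mann-Whitney AUC by direct pair counting (ties count one half).
pairCountAUC <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(cmp)
}

# Topological overlap by the defining triple loop.
bruteTOM <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + A[i, u] * A[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# Hypergeometric upper tail P[X >= k] by direct combinatorial enumeration.
bruteHyperTail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random symmetric adjacency in [0, 1] with unit diagonal.
randomAdjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("g%02d", seq_len(n)))
  A
}

# Random symmetric MI-like matrix (non-negative, zero diagonal).
randomMIMatrix <- function(n) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("g%02d", seq_len(n)))
  M
}

# Dominant right singular vector by power iteration on Z'Z (independent of
# the svd-based implementation).
powerIterationPC <- function(Z, iters = 500L) {
  v <- seq_len(ncol(Z))
  v <- v / sqrt(sum(v^2))
  G <- crossprod(Z)
  for (i in seq_len(iters)) {
    v <- G %*% v
    v <- v / sqrt(sum(v^2))
  }
  drop(v)
}

# Planted-module SimSpec shared by network/MI tests: `nmod` modules of
# `size` genes plus `nNoise` independent genes, one tissue.
plantedModuleSpec <- function(seed, nmod = 2L, size = 50L, nNoise = 100L,
                              nSamples = 200L, loading = 0.9,
                              noiseSd = 0.2) {
  mods <- data.frame(
    gene = sprintf("MOD%d_%03d", rep(seq_len(nmod), each = size),
                   rep(seq_len(size), nmod)),
    module = sprintf("m%d", rep(seq_len(nmod), each = size)),
    loading = rep(loading, nmod * size))
  genes <- c(mods$gene,
             if (nNoise) sprintf("BG%03d", seq_len(nNoise)) else character())
  SimSpec(tissues = "skin", samplesPerTissue = nSamples, genes = genes,
          noiseSdLog10 = noiseSd, modules = mods, seed = seed)
}

trueModuleLabels <- function(se) {
  m <- SummarizedExperiment::rowData(se)$module
  ifelse(is.na(m), "unassigned", m)
}
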