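#' Detection filter and log transform for network analysis
#'
#' Restricts to the requested tissues, removes genes detected (TPM > 0) in
#' fewer than `minDetectedSamples` samples, and returns
#' `log10(TPM + pseudocount)`.
#'
#' @param se `SummarizedExperiment` with a TPM assay and
#'   `colData(.)$tissue`, or a numeric matrix.
#' @param tissues Optional tissue subset (default: all samples).
#' @param minDetectedSamples Detection filter: required number of samples
#'   with TPM > 0 (reference value 650; scale to your sample count).
#' @param pseudocount Offset before the log (default 1e-4, so TPM 0 maps
#'   to exactly -4).
#' @param labels Tissue labels when `se` is a bare matrix.
#' @return Numeric log10-expression matrix, genes x samples.
#' @export
preprocessExpression <- function(se, tissues = NULL,
                                 minDetectedSamples = 650L,
                                 pseudocount = 1e-4, labels = NULL) {
  stopifnot(pseudocount > 0)
  if (is(se, "SummarizedExperiment")) {
    mat <- assay(se, 1L)
    if (is.null(labels)) labels <- colData(se)$tissue
  } else {
    mat <- as.matrix(se)
  }
  if (!is.null(tissues)) {
    if (is.null(labels)) stop("tissue labels required to subset tissues")
    keep <- labels %in% tissues
    if (!any(keep)) stop("empty-result error: no samples in the tissue subset")
    mat <- mat[, keep, drop = FALSE]
  }
  detected <- rowSums(mat > 0)
  mat <- mat[detected >= minDetectedSamples, , drop = FALSE]
  if (!nrow(mat))
    stop("empty-result error: no genes pass the detection filter")
  log10(mat + pseudocount)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Regresses log10 frequency on log10 mean connectivity over log-spaced
#' connectivity bins and returns the sign-corrected fit: R-squared, negated
#' when the slope is positive (a scale-free degree distribution must decay).
#'
#' @param k Non-negative connectivity values.
#' @param nBins Number of log-spaced bins (default 10).
#' @return List with `r2` (sign-corrected), `slope`, and the bin table.
#' @export
scaleFreeFit <- function(k, nBins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 3L)
    stop("degenerate connectivity: too few distinct positive values")
  breaks <- 10^seq(log10(min(k)), log10(max(k)), length.out = nBins + 1L)
  breaks[1L] <- breaks[1L] * (1 - 1e-9)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  tab <- data.frame(
    meanK = tapply(k, bin, mean),
    freq = as.integer(table(bin)) / length(k)
  )
  tab <- tab[!is.na(tab$meanK) & tab$freq > 0, , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("degenerate connectivity: fewer than 3 occupied bins")
  fit <- stats::lm(log10(freq) ~ log10(meanK), data = tab)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r2 = if (slope > 0) -r2 else r2, slope = slope, bins = tab)
}

#' Choose the soft-threshold power
#'
#' For each candidate power, builds the signed adjacency, computes each
#' gene's connectivity \eqn{k_i = \sum_j a_{ij} - 1}, and evaluates the
#' scale-free topology fit ([scaleFreeFit()]). Returns the smallest power
#' whose sign-corrected R-squared reaches `r2Target`; if none does, the
#' power with the best fit is returned with a warning flag.
#'
#' @param logexpr Log-expression matrix (genes x samples).
#' @param powers Candidate integer powers (default 1:20).
#' @param r2Target Required scale-free fit (default 0.8).
#' @param nBins Connectivity bins for the fit (default 10).
#' @return List with `power`, `fitTable` (power, r2, slope, meanK), and
#'   `reachedTarget`.
#' @export
pickSoftPower <- function(logexpr, powers = 1:20, r2Target = 0.8,
                          nBins = 10L) {
  stopifnot(length(powers) >= 3L)
  if (nrow(logexpr) < 20L)
    stop("at least 20 genes are required to fit scale-free topology")
  C <- safeCor(logexpr)
  base <- (1 + C) / 2
  fitTable <- data.frame(power = powers, r2 = NA_real_,
                         slope = NA_real_, meanK = NA_real_)
  for (i in seq_along(powers)) {
    A <- base^powers[i]
    diag(A) <- 1
    k <- rowSums(A) - 1
    if (length(unique(signif(k, 12))) == 1L)
      stop("degenerate connectivity: all genes equally connected")
    fit <- scaleFreeFit(k, nBins)
    fitTable$r2[i] <- fit$r2
    fitTable$slope[i] <- fit$slope
    fitTable$meanK[i] <- mean(k)
  }
  hit <- which(fitTable$r2 >= r2Target)
  if (length(hit)) {
    list(power = powers[hit[1L]], fitTable = fitTable,
         reachedTarget = TRUE)
  } else {
    warning("scale-free fit target ", r2Target,
            " not reached; using the best-fitting power")
    list(power = powers[which.max(fitTable$r2)], fitTable = fitTable,
         reachedTarget = FALSE)
  }
}

# Pearson correlation across rows with zero-variance rows mapped to 0
# (with a warning), so downstream adjacency stays defined.
safeCor <- function(logexpr) {
  sds <- apply(logexpr, 1L, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s); their correlations set to 0")
  C <- suppressWarnings(stats::cor(t(logexpr)))
  C[flat, ] <- 0
  C[, flat] <- 0
  diag(C) <- 1
  C
}

#' Signed co-expression adjacency
#'
#' \eqn{a_{ij} = ((1 + \mathrm{cor}(x_i, x_j))/2)^\beta} with Pearson
#' correlation, mapping correlation -1 to 0 and +1 to 1 monotonically;
#' the diagonal is 1. Zero-variance genes get correlation 0 (adjacency
#' \eqn{(1/2)^\beta}) with a warning.
#'
#' @param logexpr Log-expression matrix (genes x samples).
#' @param power Soft-threshold power \eqn{\beta \ge 1}.
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
signedAdjacency <- function(logexpr, power) {
  stopifnot(power >= 1)
  A <- ((1 + safeCor(logexpr)) / 2)^power
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}},\qquad k_i = \sum_{u \ne i} a_{iu},}
#' with \eqn{TOM_{ii} = 1} ("unsigned" overlap of a non-negative adjacency).
#'
#' @param adjacency Square symmetric matrix in \[0, 1\] with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tomSimilarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A) || !isSymmetric(unname(A), tol = 1e-10))
    stop("validation error: adjacency must be square and symmetric")
  if (any(A < 0) || any(A > 1 + 1e-12))
    stop("validation error: adjacency values must lie in [0, 1]")
  if (any(abs(diag(A) - 1) > 1e-12))
    stop("validation error: adjacency diagonal must be 1")
  k <- rowSums(A) - 1
  # with unit diagonal, (A %*% A)_ij counts a_ij twice; subtracting one
  # copy leaves sum_{u != i,j} a_iu a_uj + a_ij
  num <- A %*% A - A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

# WGCNA-style module colour sequence; labels beyond it fall back to
# "moduleNN".
.moduleColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cutHeightFrac` times the highest merge height.
#' Clusters smaller than `minModuleSize` become `"unassigned"`; genes whose
#' correlation with their module's eigengene (kME) falls below `kmeMin` are
#' also unassigned (module-membership cleanup), and modules shrinking below
#' the size floor are dissolved. Remaining modules are named from the
#' standard colour sequence in order of decreasing size (ties broken by the
#' lexicographically smallest member gene, so the labelling is invariant to
#' gene order).
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param logexpr Log-expression matrix (same genes) used for eigengenes
#'   and the kME filter.
#' @param minModuleSize Minimum module size (default 30).
#' @param cutHeightFrac Static cut height as a fraction of the top merge
#'   height (default 0.99).
#' @param kmeMin Minimum module membership (gene-eigengene correlation)
#'   for a gene to stay in its module (default 0.5).
#' @param power Soft power recorded in the result (for provenance only).
#' @return A [CoexpressionModules-class].
#' @export
detectModules <- function(tom, logexpr, minModuleSize = 30L,
                          cutHeightFrac = 0.99, kmeMin = 0.5,
                          power = NA_real_) {
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM must carry gene names")
  stopifnot(identical(genes, rownames(logexpr)))
  labels <- stats::setNames(rep("unassigned", length(genes)), genes)
  if (length(genes) < minModuleSize) {
    warning("fewer than ", minModuleSize,
            " genes: single unassigned partition")
    return(new("CoexpressionModules", labels = labels,
               eigengenes = matrix(numeric(), 0L, ncol(logexpr)),
               mergeHistory = emptyMergeHistory(),
               power = power, cutHeight = NA_real_))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cutHeight <- cutHeightFrac * max(hc$height)
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= minModuleSize])
  for (m in big) {
    members <- genes[cl == m]
    e <- eigengeneOf(logexpr[members, , drop = FALSE])
    kme <- apply(logexpr[members, , drop = FALSE], 1L, stats::cor, y = e)
    kept <- members[!is.na(kme) & kme >= kmeMin]
    if (length(kept) >= minModuleSize) labels[kept] <- paste0("raw", m)
  }
  labels <- relabelBySize(labels)
  eg <- computeEigengenes(logexpr, labels)
  new("CoexpressionModules", labels = labels, eigengenes = eg,
      mergeHistory = emptyMergeHistory(), power = power,
      cutHeight = cutHeight)
}

emptyMergeHistory <- function() {
  data.frame(from = character(), into = character(),
             dissimilarity = numeric(), stringsAsFactors = FALSE)
}

# Deterministic size-ordered colour labelling: biggest module first,
# ties broken by the lexicographically smallest member gene.
relabelBySize <- function(labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(labels)
  size <- vapply(mods, function(m) sum(labels == m), integer(1L))
  firstGene <- vapply(mods, function(m)
    min(names(labels)[labels == m]), character(1L))
  ord <- order(-size, firstGene)
  newNames <- c(.moduleColors,
                sprintf("module%02d", seq_len(max(0L, length(mods) -
                                                    length(.moduleColors)))))
  map <- stats::setNames(newNames[seq_along(mods)], mods[ord])
  out <- labels
  keep <- labels != "unassigned"
  out[keep] <- map[labels[keep]]
  out
}

# Unit-norm first principal component of a standardized gene x sample
# submatrix, oriented to correlate positively with the module mean profile.
eigengeneOf <- function(submat) {
  Z <- t(scale(t(submat)))
  Z[!is.finite(Z)] <- 0
  if (nrow(Z) == 1L) {
    e <- Z[1L, ]
    nrm <- sqrt(sum(e^2))
    if (nrm > 0) e <- e / nrm
    return(e)
  }
  sv <- svd(Z, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  ref <- colMeans(Z)
  if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
  e
}

computeEigengenes <- function(logexpr, labels) {
  mods <- setdiff(unique(labels), "unassigned")
  mods <- names(sort(vapply(mods, function(m) sum(labels == m),
                            integer(1L)), decreasing = TRUE))
  eg <- matrix(numeric(), 0L, ncol(logexpr),
               dimnames = list(NULL, colnames(logexpr)))
  if (!length(mods)) return(eg)
  eg <- t(vapply(mods, function(m)
    eigengeneOf(logexpr[names(labels)[labels == m], , drop = FALSE]),
    numeric(ncol(logexpr))))
  rownames(eg) <- mods
  eg
}

#' Module eigengenes of a partition
#'
#' First principal component (unit norm, sign-oriented toward the module
#' mean profile) of each module's standardized expression submatrix; a
#' single-gene module yields that gene's standardized, normalized profile.
#'
#' @param logexpr Log-expression matrix (genes x samples).
#' @param labels Named gene -> module labelling (`"unassigned"` ignored).
#' @return Matrix, modules x samples.
#' @export
eigengeneMatrix <- function(logexpr, labels) {
  computeEigengenes(logexpr, labels)
}

#' Merge closely related modules
#'
#' Iteratively merges the pair of modules with the smallest eigengene
#' dissimilarity `1 - cor` while it is below `mergeHeight`, recomputing
#' eigengenes after every merge until a fixed point. The merged module
#' keeps the larger member's label (ties: lexicographically smaller), and
#' the merge history is recorded. Global closest-pair selection makes the
#' result independent of module enumeration order.
#'
#' @param modules A [CoexpressionModules-class].
#' @param logexpr The log-expression matrix the partition was built from.
#' @param mergeHeight Eigengene dissimilarity below which modules merge
#'   (default 0.25); 0 disables merging.
#' @return An updated `CoexpressionModules`.
#' @export
mergeModules <- function(modules, logexpr, mergeHeight = 0.25) {
  stopifnot(mergeHeight >= 0, mergeHeight <= 1)
  labels <- moduleLabels(modules)
  history <- modules@mergeHistory
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2L || mergeHeight == 0) break
    eg <- computeEigengenes(logexpr, labels)
    d <- 1 - stats::cor(t(eg))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)
    # deterministic tie-break: lexicographically smallest label pair
    pairNames <- t(apply(ij, 1L, function(r)
      sort(rownames(d)[r])))
    ord <- order(pairNames[, 1L], pairNames[, 2L])
    a <- pairNames[ord[1L], 1L]
    b <- pairNames[ord[1L], 2L]
    if (d[a, b] >= mergeHeight) break
    na <- sum(labels == a)
    nb <- sum(labels == b)
    into <- if (na > nb) a else if (nb > na) b else min(a, b)
    from <- if (into == a) b else a
    labels[labels == from] <- into
    history <- rbind(history, data.frame(
      from = from, into = into, dissimilarity = d[a, b],
      stringsAsFactors = FALSE))
  }
  new("CoexpressionModules", labels = labels,
      eigengenes = computeEigengenes(logexpr, labels),
      mergeHistory = history, power = modules@power,
      cutHeight = modules@cutHeight)
}

#' Export thresholded TOM edges
#'
#' Upper-triangle edges with TOM similarity strictly above `cutoff`
#' (isolated genes carry no row).
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param cutoff Similarity threshold in \[0, 1) (reference value 0.025).
#' @return data.frame with columns `gene1`, `gene2`, `tom` (gene1 index <
#'   gene2 index, rows ordered by position).
#' @seealso [writeSIF()]
#' @export
exportTOMEdges <- function(tom, cutoff = 0.025) {
  stopifnot(cutoff >= 0, cutoff < 1)
  genes <- rownames(tom)
  up <- which(upper.tri(tom) & tom > cutoff, arr.ind = TRUE)
  data.frame(gene1 = genes[up[, 1L]], gene2 = genes[up[, 2L]],
             tom = tom[up], stringsAsFactors = FALSE)
}

#' Write an edge list in SIF format
#'
#' @param edges data.frame with two node columns (and optionally more).
#' @param path Output path.
#' @param relation Interaction type written between the nodes.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(edges, path, relation = "tom") {
  writeLines(paste(edges[[1L]], relation, edges[[2L]]), path)
  invisible(path)
}

#' Per-tissue log2 fold-expression profile
#'
#' For each gene: mean TPM per tissue, referenced to the grand mean of the
#' per-tissue means, as `log2((tissue mean + pseudocount) /
#' (reference + pseudocount))`.
#'
#' @inheritParams callAssociations
#' @param pseudocount Offset guarding the ratio (default 1e-4).
#' @return Matrix, genes x tissues.
#' @export
tissueFoldProfile <- function(se, genes = NULL, pseudocount = 1e-4,
                              labels = NULL) {
  if (is(se, "SummarizedExperiment")) {
    mat <- assay(se, 1L)
    if (is.null(labels)) labels <- colData(se)$tissue
  } else {
    mat <- as.matrix(se)
  }
  tissues <- sort(unique(labels))
  if (length(tissues) < 2L) stop("at least 2 tissues are required")
  if (is.null(genes)) genes <- rownames(mat)
  means <- vapply(tissues, function(t)
    rowMeans(mat[genes, labels == t, drop = FALSE]),
    numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, tissues))
  ref <- rowMeans(means)
  log2((means + pseudocount) / (ref + pseudocount))
}
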