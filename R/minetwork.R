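#' Mutual information between two expression profiles
#'
#' Two estimators are provided. `"gaussian_rank"` (default) transforms each
#' vector to normal scores of its mid-ranks and returns the Gaussian MI
#' \eqn{-\tfrac12 \ln(1 - \rho^2)} of their Pearson correlation; being
#' rank-based it is invariant under strictly monotone transforms, and a
#' perfect dependence is capped at the documented ceiling
#' \eqn{\tfrac12 \ln n}. `"binned"` is the plug-in estimate over an
#' equal-frequency 2-D histogram with Miller-Madow bias correction, floored
#' at 0; the default bin count per axis is \eqn{\lceil n^{1/3} \rceil}.
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param estimator `"gaussian_rank"` or `"binned"`.
#' @param bins Bin count per axis for the binned estimator (default
#'   \eqn{\lceil n^{1/3} \rceil}).
#' @return MI in nats (>= 0); a constant input yields 0 with a warning.
#' @export
mutualInformation <- function(x, y,
                              estimator = c("gaussian_rank", "binned"),
                              bins = NULL) {
  estimator <- match.arg(estimator)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10L) stop("at least 10 observations are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input vector: MI = 0")
    return(0)
  }
  if (estimator == "gaussian_rank") {
    r <- stats::cor(normalScores(x), normalScores(y))
    gaussianMI(r, n)
  } else {
    if (is.null(bins)) bins <- ceiling(n^(1 / 3))
    binnedMI(x, y, bins)
  }
}

normalScores <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

gaussianMI <- function(r, n) {
  cap <- 0.5 * log(n)
  if (!is.finite(r)) return(0)
  r2 <- min(r^2, 1)
  if (r2 >= 1) return(cap)
  min(-0.5 * log1p(-r2), cap)
}

binnedMI <- function(x, y, bins) {
  n <- length(x)
  bx <- equalFreqBin(x, bins)
  by <- equalFreqBin(y, bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- H(px) + H(py) - H(joint)
  # Miller-Madow: H_mm = H + (K - 1) / (2n) per marginal/joint entropy
  mm <- mi + (sum(px > 0) - 1) / (2 * n) + (sum(py > 0) - 1) / (2 * n) -
    (sum(joint > 0) - 1) / (2 * n)
  max(mm, 0)
}

equalFreqBin <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) br <- range(x) + c(-1, 1)
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Pairwise mutual-information matrix
#'
#' @param logexpr Log-expression matrix, genes x samples (>= 3 genes).
#' @inheritParams mutualInformation
#' @return Symmetric MI matrix with zero diagonal.
#' @export
miMatrix <- function(logexpr, estimator = c("gaussian_rank", "binned"),
                     bins = NULL) {
  estimator <- match.arg(estimator)
  if (nrow(logexpr) < 3L) stop("at least 3 genes are required")
  n <- ncol(logexpr)
  genes <- rownames(logexpr)
  flat <- apply(logexpr, 1L, function(v) length(unique(v)) == 1L)
  if (any(flat))
    warning(sum(flat), " constant gene(s): their MI set to 0")
  if (estimator == "gaussian_rank") {
    scores <- t(apply(logexpr, 1L, normalScores))
    C <- suppressWarnings(stats::cor(t(scores)))
    C[flat, ] <- 0
    C[, flat] <- 0
    M <- matrix(vapply(C, gaussianMI, numeric(1L), n = n),
                nrow(C), ncol(C), dimnames = list(genes, genes))
  } else {
    G <- nrow(logexpr)
    M <- matrix(0, G, G, dimnames = list(genes, genes))
    for (i in seq_len(G - 1L)) {
      for (j in (i + 1L):G) {
        if (flat[i] || flat[j]) next
        M[i, j] <- M[j, i] <- binnedMI(logexpr[i, ], logexpr[j, ],
                                       if (is.null(bins))
                                         ceiling(n^(1 / 3)) else bins)
      }
    }
  }
  diag(M) <- 0
  M
}

#' Permutation significance threshold for mutual information
#'
#' Null MI distribution by sample-label permutation: in each round one gene
#' row (cycled through the matrix) is shuffled and its MI against every
#' other gene recomputed; the pooled null values (capped at `maxPairs`)
#' yield the `1 - alpha` quantile as threshold. Deterministic given the
#' seed.
#'
#' @inheritParams miMatrix
#' @param nPermutations Permutation rounds (>= 20, default 100).
#' @param alpha Tail probability (default 0.01).
#' @param maxPairs Cap on pooled null MI values (default 10000).
#' @param seed Integer seed (default 1).
#' @return The MI significance threshold.
#' @export
miThreshold <- function(logexpr, nPermutations = 100L, alpha = 0.01,
                        estimator = c("gaussian_rank", "binned"),
                        bins = NULL, maxPairs = 10000L, seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(nPermutations >= 20L, alpha > 0, alpha < 1)
  G <- nrow(logexpr)
  set.seed(as.integer(seed))
  pooled <- numeric(0L)
  for (b in seq_len(nPermutations)) {
    g <- ((b - 1L) %% G) + 1L
    perm <- sample(ncol(logexpr))
    null <- vapply(setdiff(seq_len(G), g), function(j)
      suppressWarnings(
        mutualInformation(logexpr[g, perm], logexpr[j, ],
                          estimator = estimator, bins = bins)),
      numeric(1L))
    pooled <- c(pooled, null)
    if (length(pooled) >= maxPairs) {
      pooled <- pooled[seq_len(maxPairs)]
      break
    }
  }
  unname(stats::quantile(pooled, probs = 1 - alpha, type = 7))
}

#' Maximal-MI-neighbour network (c3net selection rule)
#'
#' Zeroes all MI values at or below the threshold, then lets every gene
#' keep only the edge to its maximal remaining MI neighbour (ties resolved
#' toward the lexicographically smallest gene ID); the union of the picks,
#' deduplicated, is the undirected edge set, so there are at most as many
#' edges as genes. Connected components label the sub-networks.
#'
#' @param x Log-expression matrix (MI is computed with `estimator`) or a
#'   precomputed symmetric MI matrix.
#' @param threshold MI significance threshold (see [miThreshold()]).
#' @inheritParams miMatrix
#' @return An [MINetwork-class].
#' @examples
#' m <- matrix(c(0, .9, .1, .9, 0, .2, .1, .2, 0), 3, 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
#' net <- c3netNetwork(m, threshold = 0.15)
#' miEdges(net)
#' @export
c3netNetwork <- function(x, threshold = 0,
                         estimator = c("gaussian_rank", "binned"),
                         bins = NULL) {
  if (nrow(x) == ncol(x) &&
      !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
      isSymmetric(unname(as.matrix(x)), tol = 1e-10)) {
    M <- as.matrix(x)
  } else {
    M <- miMatrix(x, estimator = match.arg(estimator), bins = bins)
  }
  genes <- rownames(M)
  if (is.null(genes)) stop("MI matrix must carry gene names")
  diag(M) <- 0
  M[M <= threshold] <- 0
  picks <- list()
  for (i in seq_along(genes)) {
    row <- M[i, ]
    best <- max(row)
    if (best <= 0) next
    cand <- genes[row == best]
    j <- min(cand)  # lexicographic tie-break
    picks[[length(picks) + 1L]] <-
      sort(c(genes[i], j))
  }
  if (length(picks)) {
    em <- unique(do.call(rbind, picks))
    edges <- data.frame(gene1 = em[, 1L], gene2 = em[, 2L],
                        mi = M[cbind(em[, 1L], em[, 2L])],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        mi = numeric(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = genes)
  comp <- igraph::components(g)
  membership <- stats::setNames(as.integer(comp$membership), genes)
  new("MINetwork", edges = edges, membership = membership,
      threshold = threshold)
}

#' Sub-network (connected component) of a gene
#'
#' @param network An [MINetwork-class].
#' @param gene Gene ID present in the network.
#' @return List with `componentId`, `members`, `size`, `rank` (1 = largest
#'   component, ties share the better rank), `isLargest`, and the full
#'   decreasing `componentSizes` vector.
#' @export
subnetworkOf <- function(network, gene) {
  stopifnot(is(network, "MINetwork"))
  membership <- network@membership
  if (!gene %in% names(membership))
    stop("unknown gene: ", gene)
  id <- membership[[gene]]
  members <- names(membership)[membership == id]
  sizes <- componentSizes(network)
  size <- length(members)
  list(componentId = id, members = members, size = size,
       rank = sum(sizes > size) + 1L,
       isLargest = size == max(sizes),
       componentSizes = sizes)
}
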