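#' Thresholds of the composite tissue-association criterion
#'
#' A gene is called highly expressed in a tissue when, comparing that
#' tissue's samples against all remaining samples (one-vs-rest), the
#' Wilcoxon rank-sum p-value is below `pMax`, the fold change of group
#' means is at least `fcMin`, and the ROC AUC of a one-feature linear
#' discriminant is at least `aucMin`. Defaults are the reference criterion:
#' p < 1e-10, fold change >= 25, AUC >= 0.85.
#'
#' @param pMax Upper p-value bound (exclusive), in (0, 1).
#' @param fcMin Lower fold-change bound (inclusive), > 0.
#' @param aucMin Lower AUC bound (inclusive), in \[0.5, 1\].
#' @param pseudocount Added to both group means before the ratio, so the
#'   fold change of an all-zero gene is 1 (default 1e-4, matching the
#'   constant used for the log10 transform elsewhere in the pipeline).
#' @return A list with the four thresholds.
#' @export
associationCriteria <- function(pMax = 1e-10, fcMin = 25, aucMin = 0.85,
                                pseudocount = 1e-4) {
  stopifnot(pMax > 0, pMax < 1, fcMin > 0, aucMin >= 0.5, aucMin <= 1,
            pseudocount > 0)
  list(pMax = pMax, fcMin = fcMin, aucMin = aucMin,
       pseudocount = pseudocount)
}

#' One-vs-rest Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test of the target tissue's samples against
#' all remaining samples. Small untied groups are tested by exact
#' enumeration, larger or tied ones by the normal approximation with
#' mid-rank tie correction and continuity correction (the behaviour of
#' [stats::wilcox.test()]); an entirely constant input yields p = 1.
#'
#' @param values Numeric per-sample expression.
#' @param labels Tissue label per sample.
#' @param target Target tissue.
#' @return Two-sided p-value.
#' @export
wilcoxonOneVsRest <- function(values, labels, target) {
  inTarget <- labels == target
  if (!any(inTarget) || all(inTarget))
    stop("both the target group and the rest must be non-empty")
  x <- values[inTarget]
  y <- values[!inTarget]
  if (length(unique(c(x, y))) == 1L) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       correct = TRUE)$p.value)
  if (is.nan(p)) 1 else min(p, 1)
}

#' One-vs-rest fold change of group means
#'
#' Ratio of target-group mean TPM to rest-group mean TPM, each offset by a
#' pseudocount so that zero-expression genes yield a well-defined fold of 1.
#'
#' @inheritParams wilcoxonOneVsRest
#' @param pseudocount Offset added to both means (default 1e-4).
#' @return `(mean(target) + pseudocount) / (mean(rest) + pseudocount)`.
#' @export
foldChange <- function(values, labels, target, pseudocount = 1e-4) {
  inTarget <- labels == target
  if (!any(inTarget) || all(inTarget))
    stop("both the target group and the rest must be non-empty")
  (mean(values[inTarget]) + pseudocount) /
    (mean(values[!inTarget]) + pseudocount)
}

#' ROC AUC of a one-feature linear discriminant
#'
#' Fits a single-feature linear discriminant (pooled within-class variance,
#' priors proportional to class sizes) with the target tissue as positive
#' class and returns the resubstitution ROC AUC of the discriminant score.
#' For one feature the score is a monotone transform of the feature whose
#' direction is the sign of the class-mean difference, so the AUC equals the
#' rank-based (Mann-Whitney) AUC or its complement; mid-ranks handle ties.
#' With zero pooled variance both classes are constant and the AUC is
#' defined directly from the two constants (1, 0, or 0.5 on equality).
#'
#' @inheritParams wilcoxonOneVsRest
#' @return AUC in \[0, 1\].
#' @export
ldaAuc <- function(values, labels, target) {
  inTarget <- labels == target
  if (!any(inTarget) || all(inTarget))
    stop("both the target group and the rest must be non-empty")
  x <- values[inTarget]
  y <- values[!inTarget]
  n1 <- length(x)
  n0 <- length(y)
  v1 <- if (n1 > 1L) stats::var(x) else 0
  v0 <- if (n0 > 1L) stats::var(y) else 0
  pooled <- ((n1 - 1) * v1 + (n0 - 1) * v0) / max(n1 + n0 - 2, 1L)
  if (!is.finite(pooled) || pooled == 0) {
    # both classes constant: AUC from the two class constants
    if (x[1L] > y[1L]) return(1)
    if (x[1L] < y[1L]) return(0)
    return(0.5)
  }
  direction <- mean(x) - mean(y)
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  if (direction < 0) auc <- 1 - auc
  if (direction == 0) auc <- 0.5
  auc
}

#' Call tissue-associated genes across all tissues
#'
#' Applies the composite criterion (Wilcoxon p, fold change, LDA AUC; see
#' [associationCriteria()]) to every requested gene in every tissue,
#' one-vs-rest.
#'
#' @param se A `SummarizedExperiment` with a TPM assay and a
#'   `colData(.)$tissue` column (or a numeric matrix plus `labels`).
#' @param genes Genes to test (default: all rows).
#' @param criteria Output of [associationCriteria()].
#' @param labels Tissue label per sample; defaults to `colData(se)$tissue`.
#' @return A [TissueAssociation-class].
#' @examples
#' sim <- simulateTissueExperiment(demoSimSpec(nTissues = 3,
#'   samplesPerTissue = 20, nMarkers = 3, nNullOR = 10))
#' callAssociations(sim$se)
#' @export
callAssociations <- function(se, genes = NULL,
                             criteria = associationCriteria(),
                             labels = NULL) {
  if (is(se, "SummarizedExperiment")) {
    mat <- assay(se, 1L)
    if (is.null(labels)) labels <- colData(se)$tissue
  } else {
    mat <- as.matrix(se)
  }
  if (is.null(labels))
    stop("sample tissue labels are required")
  if (length(labels) != ncol(mat))
    stop("annotations must cover all samples")
  if (is.null(genes)) genes <- rownames(mat)
  if (!length(genes)) stop("empty gene subset")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  tissues <- sort(unique(labels))
  nRec <- length(genes) * length(tissues)
  tab <- data.frame(
    gene = rep(genes, each = length(tissues)),
    tissue = rep(tissues, times = length(genes)),
    p_value = numeric(nRec), fold_change = numeric(nRec),
    lda_auc = numeric(nRec), stringsAsFactors = FALSE)
  i <- 0L
  for (g in genes) {
    v <- mat[g, ]
    for (t in tissues) {
      i <- i + 1L
      tab$p_value[i] <- wilcoxonOneVsRest(v, labels, t)
      tab$fold_change[i] <- foldChange(v, labels, t, criteria$pseudocount)
      tab$lda_auc[i] <- ldaAuc(v, labels, t)
    }
  }
  tab$passes <- tab$p_value < criteria$pMax &
    tab$fold_change >= criteria$fcMin & tab$lda_auc >= criteria$aucMin
  new("TissueAssociation", table = tab, criteria = criteria)
}

#' Gene x tissue z-score matrix of median expression
#'
#' For each gene, the median TPM per tissue is z-scored across tissues
#' (sample sd, n-1 denominator); a gene constant across tissues maps to an
#' all-zero row. This is the matrix behind marker-gene heatmaps.
#'
#' @inheritParams callAssociations
#' @return Numeric matrix, genes x tissues.
#' @export
tissueZscore <- function(se, genes = NULL, labels = NULL) {
  if (is(se, "SummarizedExperiment")) {
    mat <- assay(se, 1L)
    if (is.null(labels)) labels <- colData(se)$tissue
  } else {
    mat <- as.matrix(se)
  }
  tissues <- sort(unique(labels))
  if (length(tissues) < 2L) stop("at least 2 tissues are required")
  if (is.null(genes)) genes <- rownames(mat)
  med <- vapply(tissues, function(t)
    apply(mat[genes, labels == t, drop = FALSE], 1L, stats::median),
    numeric(length(genes)))
  med <- matrix(med, nrow = length(genes),
                dimnames = list(genes, tissues))
  t(apply(med, 1L, function(row) {
    s <- stats::sd(row)
    if (!is.finite(s) || s == 0) rep(0, length(row))
    else (row - mean(row)) / s
  }))
}
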