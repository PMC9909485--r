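#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_i = \min_{j \ge \mathrm{rank}(i)} m\, p_{(j)} / j}, capped at 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, order-preserving.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For every annotated term, tests whether the query gene set overlaps the
#' term's genes more than expected by chance: with a universe of `N` genes
#' of which `K` carry the term and a query of size `n` overlapping in `k`,
#' the p-value is the hypergeometric upper tail \eqn{P[X \ge k]} (the
#' observed overlap included). Benjamini-Hochberg q-values are computed over
#' all tested terms; a record passes when `q <= qMax` and `k >= minOverlap`
#' (both bounds inclusive).
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param annotation Named list of term gene sets (e.g. from [readGMT()]).
#' @param universe Background gene universe (e.g. all genes passing the
#'   detection filter).
#' @param qMax q-value threshold (default 0.05).
#' @param minOverlap Minimum overlap count for reporting (default 10).
#' @return data.frame with one row per tested term (`term`, `k`, `n`, `K`,
#'   `N`, `p_value`, `q_value`, `passes`), sorted by q then p.
#' @seealso [filterEnrichment()]
#' @export
enrichHypergeometric <- function(query, annotation, universe,
                                 qMax = 0.05, minOverlap = 10L) {
  stopifnot(qMax > 0, qMax <= 1, minOverlap >= 1L)
  if (!length(query)) stop("empty query gene set")
  if (!length(annotation)) stop("empty annotation")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    termGenes <- intersect(annotation[[term]], universe)
    K <- length(termGenes)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, termGenes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no annotated term overlaps the universe")
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out$passes <- out$q_value <= qMax & out$k >= minOverlap
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment records to the reporting thresholds
#'
#' @param records Output of [enrichHypergeometric()].
#' @param qMax,minOverlap Reporting thresholds (defaults 0.05 and 10,
#'   both inclusive).
#' @return The passing subset.
#' @export
filterEnrichment <- function(records, qMax = 0.05, minOverlap = 10L) {
  records[records$q_value <= qMax & records$k >= minOverlap, ,
          drop = FALSE]
}
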