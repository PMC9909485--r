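#' Select genes by a symbol prefix/suffix rule
#'
#' Applies the symbol rule used to pull protein-coding olfactory receptor
#' genes out of pathway gene lists: keep symbols that start with a required
#' prefix and do not end with a forbidden suffix (HGNC marks pseudogenes
#' with a terminal "P", so the suffix match is case-insensitive by default).
#'
#' @param geneIds Character vector of gene symbols (order is preserved).
#' @param prefix Required prefix (default `"OR"`).
#' @param forbiddenSuffix Forbidden terminal string (default `"P"`); set to
#'   `NULL` to disable.
#' @param ignoreSuffixCase Match the suffix case-insensitively (default
#'   `TRUE`, so both "P" and "p" endings are excluded).
#' @param allowLists Optional list of character vectors (e.g. pathway gene
#'   lists); when given, only genes in their union are considered.
#' @return The selected subset of `geneIds`, in input order.
#' @examples
#' selectGenesByRule(c("OR10A6", "OR5P2", "TAS2R1", "OR2A7P"))
#' @export
selectGenesByRule <- function(geneIds, prefix = "OR", forbiddenSuffix = "P",
                              ignoreSuffixCase = TRUE, allowLists = NULL) {
  stopifnot(nzchar(prefix))
  pool <- geneIds
  if (!is.null(allowLists))
    pool <- pool[pool %in% unique(unlist(allowLists))]
  keep <- startsWith(pool, prefix)
  if (!is.null(forbiddenSuffix) && nzchar(forbiddenSuffix)) {
    ends <- if (ignoreSuffixCase)
      endsWith(toupper(pool), toupper(forbiddenSuffix))
    else endsWith(pool, forbiddenSuffix)
    keep <- keep & !ends
  }
  pool[keep]
}
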