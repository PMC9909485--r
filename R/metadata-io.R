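#' Read a sample metadata table
#'
#' Reads a tab-separated sample annotation table and returns one annotation
#' row per sample, keyed by sample ID, with the tissue label and any further
#' columns (sex, age band, death classification, ...) carried along.
#'
#' @param path Path to a TSV file with a header row.
#' @param sampleCol,tissueCol Names of the sample-ID and tissue columns.
#' @return A [S4Vectors::DataFrame] with sample IDs as rownames and at least
#'   a `tissue` column.
#' @details Rows with an empty tissue label are dropped with a warning that
#'   reports the count; a duplicated sample ID is a validation error and a
#'   missing named column a format error.
#' @seealso [filterTissues()], [recategorizeSamples()]
#' @export
readSampleMetadata <- function(path, sampleCol = "sample_id",
                               tissueCol = "tissue") {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = "character")
  for (col in c(sampleCol, tissueCol))
    if (!col %in% names(tab))
      stop("format error: metadata lacks column '", col, "'")
  empty <- is.na(tab[[tissueCol]]) | trimws(tab[[tissueCol]]) == ""
  if (any(empty)) {
    warning("dropping ", sum(empty), " sample(s) with empty tissue label")
    tab <- tab[!empty, , drop = FALSE]
  }
  if (!nrow(tab)) stop("empty-result error: no annotated samples left")
  if (anyDuplicated(tab[[sampleCol]]))
    stop("validation error: duplicate sample IDs in metadata")
  out <- S4Vectors::DataFrame(tab[, setdiff(names(tab), sampleCol),
                                  drop = FALSE],
                              row.names = tab[[sampleCol]])
  names(out)[names(out) == tissueCol] <- "tissue"
  out
}

#' Drop tissues with too few samples
#'
#' Removes every sample belonging to a tissue represented by fewer than
#' `minSamplesPerTissue` samples (the threshold itself is retained: a tissue
#' with exactly the minimum survives).
#'
#' @param annot A `DataFrame`/`data.frame` with a `tissue` column and sample
#'   IDs as rownames (as returned by [readSampleMetadata()]).
#' @param minSamplesPerTissue Minimum per-tissue sample count (default 100).
#' @return The filtered annotation; erroring if no tissue survives.
#' @export
filterTissues <- function(annot, minSamplesPerTissue = 100L) {
  stopifnot(minSamplesPerTissue >= 1L)
  if (!nrow(annot)) stop("empty-result error: no samples to filter")
  counts <- table(annot$tissue)
  keep <- names(counts)[counts >= minSamplesPerTissue]
  if (!length(keep))
    stop("empty-result error: every tissue has fewer than ",
         minSamplesPerTissue, " samples")
  annot[annot$tissue %in% keep, , drop = FALSE]
}

#' Re-categorize flagged samples into their own tissue label
#'
#' Samples whose metadata attribute `attrCol` equals `sourceValue` are
#' re-labelled with `targetTissue` (the motivating case: cultured-fibroblast
#' samples filed under a skin category get their own "cultured fibroblast"
#' tissue). All other samples are untouched; the total sample count is
#' conserved and the operation is idempotent.
#'
#' @param annot Sample annotation with a `tissue` column.
#' @param attrCol Name of the metadata column carrying the flag.
#' @param sourceValue Attribute value that marks samples to re-label.
#' @param targetTissue New tissue label for matching samples.
#' @return The re-labelled annotation.
#' @export
recategorizeSamples <- function(annot, attrCol, sourceValue,
                                targetTissue = "cultured fibroblast") {
  if (!attrCol %in% names(annot))
    stop("format error: annotation lacks column '", attrCol, "'")
  hit <- !is.na(annot[[attrCol]]) & annot[[attrCol]] == sourceValue
  annot$tissue[hit] <- targetTissue
  annot
}
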