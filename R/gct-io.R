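#' Read a GCT v1.2 expression matrix
#'
#' Parses the GCT v1.2 layout used to distribute bulk TPM matrices
#' (line 1 `#1.2`; line 2 `<nGenes> <nSamples>`; then a header row
#' `Name`, `Description`, sample IDs, followed by one row per gene).
#'
#' @param path Path to a GCT file.
#' @return A [SummarizedExperiment::SummarizedExperiment] with a `tpm`
#'   assay, gene IDs as rownames, sample IDs as colnames, and the GCT
#'   `Description` column kept in `rowData(.)$Description`.
#' @details The declared dimensions are checked against the parsed body
#'   (mismatch is a format error); duplicate gene or sample IDs, negative
#'   or non-finite values are validation errors.
#' @examples
#' spec <- demoSimSpec(nTissues = 2, samplesPerTissue = 5, nNullOR = 10,
#'                     nMarkers = 2)
#' sim <- simulateTissueExperiment(spec)
#' f <- tempfile(fileext = ".gct")
#' writeGCT(sim$se, f)
#' se <- readGCT(f)
#' dim(se)
#' @seealso [writeGCT()]
#' @export
readGCT <- function(path) {
  if (!file.exists(path)) stop("GCT file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  version <- readLines(con, n = 1L)
  if (!identical(trimws(version), "#1.2"))
    stop("format error: expected GCT version line '#1.2', got '",
         version, "'")
  dims <- scan(con, what = integer(), n = 2L, quiet = TRUE)
  if (length(dims) != 2L || any(is.na(dims)))
    stop("format error: GCT dimension line must hold two integers")
  body <- utils::read.delim(con, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = "character")
  if (!all(c("Name", "Description") %in% names(body)[1:2]))
    stop("format error: GCT header must start with Name, Description")
  if (nrow(body) != dims[1L])
    stop("format error: GCT declares ", dims[1L], " genes but contains ",
         nrow(body), " rows")
  if (ncol(body) - 2L != dims[2L])
    stop("format error: GCT declares ", dims[2L], " samples but contains ",
         ncol(body) - 2L, " value columns")
  geneIds <- body$Name
  if (anyDuplicated(geneIds))
    stop("validation error: duplicate gene IDs in GCT")
  sampleIds <- names(body)[-(1:2)]
  if (anyDuplicated(sampleIds))
    stop("validation error: duplicate sample IDs in GCT")
  values <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("validation error: non-finite expression values in GCT")
  if (any(values < 0))
    stop("validation error: negative expression values in GCT")
  dimnames(values) <- list(geneIds, sampleIds)
  SummarizedExperiment(
    assays = list(tpm = values),
    rowData = S4Vectors::DataFrame(Description = body$Description,
                                   row.names = geneIds)
  )
}

#' Write a GCT v1.2 expression matrix
#'
#' @param se A `SummarizedExperiment` (first assay is written) or a numeric
#'   matrix with dimnames.
#' @param path Output path.
#' @param digits Significant digits used for serialization (values are
#'   preserved losslessly up to this precision on a round-trip).
#' @return `path`, invisibly.
#' @seealso [readGCT()]
#' @export
writeGCT <- function(se, path, digits = 6L) {
  if (is(se, "SummarizedExperiment")) {
    values <- assay(se, 1L)
    desc <- rowData(se)$Description
  } else {
    values <- as.matrix(se)
    desc <- NULL
  }
  if (is.null(desc)) desc <- rep("na", nrow(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(values)),
                   collapse = "\t"), con)
  formatted <- formatC(signif(values, digits), format = "g",
                       digits = digits)
  lines <- paste(rownames(values), desc,
                 apply(formatted, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
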