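#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect (term, description, member genes)
#' used for gene-set annotation files.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term -> genes), carrying the
#'   term descriptions in `attr(., "description")`.
#' @details A term with no member genes is dropped with a warning; a
#'   duplicated term ID is a validation error.
#' @seealso [writeGMT()], [enrichHypergeometric()]
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(terms))
    stop("validation error: duplicate term IDs in GMT")
  desc <- vapply(fields, function(f)
    if (length(f) >= 2L) f[2L] else "", character(1L))
  sets <- lapply(fields, function(f)
    if (length(f) > 2L) f[-(1:2)][nzchar(f[-(1:2)])] else character())
  names(sets) <- terms
  names(desc) <- terms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(utils::head(terms[empty], 5L), collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors (term -> genes).
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions
#'   (defaults to `attr(sets, "description")`, else `"na"`).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, descriptions[[term]], sets[[term]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
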