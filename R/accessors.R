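#' @rdname TissueAssociation-class
#' @aliases assocTable,TissueAssociation-method
#' @export
setMethod("assocTable", "TissueAssociation", function(x) x@table)

#' @rdname TissueAssociation-class
#' @export
setMethod("passingGenes", "TissueAssociation", function(x) {
  unique(x@table$gene[x@table$passes])
})

#' @rdname TissueAssociation-class
#' @export
setMethod("passingTissues", "TissueAssociation", function(x) {
  unique(x@table$tissue[x@table$passes])
})

#' @rdname TissueAssociation-class
#' @export
setMethod("show", "TissueAssociation", function(object) {
  tab <- object@table
  cfg <- object@criteria
  cat("TissueAssociation with", nrow(tab), "(gene, tissue) records\n")
  cat(sprintf("  criteria: p < %g, fold change >= %g, LDA AUC >= %g\n",
              cfg$pMax, cfg$fcMin, cfg$aucMin))
  cat(sprintf("  %d genes pass in >= 1 tissue; %d tissues have >= 1 passing gene\n",
              length(passingGenes(object)), length(passingTissues(object))))
})

#' @rdname CoexpressionModules-class
#' @export
setMethod("moduleLabels", "CoexpressionModules", function(x) x@labels)

#' @rdname CoexpressionModules-class
#' @export
setMethod("moduleEigengenes", "CoexpressionModules", function(x) x@eigengenes)

#' @rdname CoexpressionModules-class
#' @export
setMethod("moduleSizes", "CoexpressionModules", function(x) {
  lab <- x@labels[x@labels != "unassigned"]
  if (!length(lab)) return(integer())
  sz <- sort(table(lab), decreasing = TRUE)
  stats::setNames(as.integer(sz), names(sz))
})

#' @rdname CoexpressionModules-class
#' @export
setMethod("show", "CoexpressionModules", function(object) {
  sz <- moduleSizes(object)
  cat("CoexpressionModules over", length(object@labels), "genes\n")
  cat("  soft power:", object@power, "  cut height:",
      signif(object@cutHeight, 4), "\n")
  cat("  ", length(sz), " modules (",
      sum(object@labels == "unassigned"), " unassigned)\n", sep = "")
  if (length(sz)) {
    shown <- utils::head(sz, 8)
    cat("  sizes:", paste(sprintf("%s=%d", names(shown), shown),
                          collapse = ", "),
        if (length(sz) > 8) "...\n" else "\n")
  }
})

#' @rdname MINetwork-class
#' @export
setMethod("miEdges", "MINetwork", function(x) x@edges)

#' @rdname MINetwork-class
#' @export
setMethod("componentSizes", "MINetwork", function(x) {
  sz <- table(x@membership)
  sort(stats::setNames(as.integer(sz), names(sz)), decreasing = TRUE)
})

#' @rdname MINetwork-class
#' @export
setMethod("show", "MINetwork", function(object) {
  sz <- componentSizes(object)
  cat("MINetwork with", length(object@membership), "genes and",
      nrow(object@edges), "edges\n")
  cat("  MI threshold:", signif(object@threshold, 4), "\n")
  cat("  ", length(sz), " components; largest: ", max(c(sz, 0L)), " genes\n",
      sep = "")
})

#' @rdname SimTruth-class
#' @export
setMethod("truthMarkers", "SimTruth", function(x) x@markers)

#' @rdname SimTruth-class
#' @export
setMethod("truthModules", "SimTruth", function(x) x@modules)

#' @rdname SimTruth-class
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@markers), "planted markers,",
      nrow(object@modules), "module gene assignments\n")
})

#' @rdname SimSpec-class
#' @param object A `SimSpec`.
#' @export
setMethod("show", "SimSpec", function(object) {
  cat("SimSpec:", length(object@tissues), "tissues,",
      sum(object@samplesPerTissue), "samples,",
      length(object@genes), "genes\n")
  cat("  markers:", nrow(object@markers),
      "  module genes:", nrow(object@modules),
      "  seed:", object@seed, "\n")
})
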