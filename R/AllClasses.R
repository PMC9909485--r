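#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Specification of a synthetic multi-tissue TPM experiment
#'
#' Describes the generative model behind [simulateTissueExperiment()]: a
#' log10-normal baseline per gene, additive latent co-expression factors,
#' planted tissue-specific markers (multiplicative fold change on the TPM
#' scale), and per-gene dropout (zero inflation) emulating sparsely expressed
#' receptor genes.
#'
#' @slot tissues Character vector of tissue labels.
#' @slot samplesPerTissue Named integer vector, samples per tissue.
#' @slot genes Character vector of gene symbols.
#' @slot baselineLog10Mean,baselineLog10Sd Mean and sd of the per-gene
#'   baseline expression level on the log10 TPM scale.
#' @slot noiseSdLog10 Sample-level Gaussian noise sd on the log10 scale.
#' @slot dropoutProb Named numeric vector in \[0, 1\], per-gene probability
#'   that a measurement is zeroed (dropout never applies to a marker gene's
#'   target-tissue samples, so planted signal survives).
#' @slot markers data.frame with columns `gene`, `tissue`, `fold` (> 1).
#' @slot modules data.frame with columns `gene`, `module`, `loading`
#'   (loadings in (0, 1\]); gene sets are disjoint across modules.
#' @slot moduleFactorSd Named numeric vector, latent factor sd per module.
#' @slot seed Integer seed making generation deterministic.
#'
#' @seealso [SimSpec()], [simulateTissueExperiment()], [demoSimSpec()]
#' @exportClass SimSpec
setClass("SimSpec", representation(
  tissues = "character",
  samplesPerTissue = "integer",
  genes = "character",
  baselineLog10Mean = "numeric",
  baselineLog10Sd = "numeric",
  noiseSdLog10 = "numeric",
  dropoutProb = "numeric",
  markers = "data.frame",
  modules = "data.frame",
  moduleFactorSd = "numeric",
  seed = "integer"
))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (anyDuplicated(object@tissues)) msg <- c(msg, "duplicated tissue labels")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated gene symbols")
  if (length(object@samplesPerTissue) != length(object@tissues))
    msg <- c(msg, "samplesPerTissue must have one entry per tissue")
  if (any(object@samplesPerTissue < 1L))
    msg <- c(msg, "samplesPerTissue must be >= 1")
  if (length(object@dropoutProb) != length(object@genes))
    msg <- c(msg, "dropoutProb must have one entry per gene")
  if (any(object@dropoutProb < 0 | object@dropoutProb > 1))
    msg <- c(msg, "dropoutProb must lie in [0, 1]")
  if (nrow(object@markers)) {
    if (!all(object@markers$gene %in% object@genes))
      msg <- c(msg, "marker genes must be generated genes")
    if (!all(object@markers$tissue %in% object@tissues))
      msg <- c(msg, "marker tissues must be generated tissues")
    if (any(object@markers$fold <= 1))
      msg <- c(msg, "marker folds must be > 1")
  }
  if (nrow(object@modules)) {
    if (!all(object@modules$gene %in% object@genes))
      msg <- c(msg, "module genes must be generated genes")
    if (anyDuplicated(object@modules$gene))
      msg <- c(msg, "module gene sets must be disjoint")
    if (any(object@modules$loading <= 0 | object@modules$loading > 1))
      msg <- c(msg, "module loadings must lie in (0, 1]")
    if (!all(unique(object@modules$module) %in% names(object@moduleFactorSd)))
      msg <- c(msg, "every module needs a factor sd")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic experiment
#'
#' Machine-readable record of what [simulateTissueExperiment()] planted:
#' marker (gene, tissue, fold) triples, gene-to-module assignments, and the
#' scalar generator parameters, so downstream recovery can be scored.
#'
#' @slot markers data.frame with columns `gene`, `tissue`, `fold`.
#' @slot modules data.frame with columns `gene`, `module`.
#' @slot params data.frame with columns `key`, `value` (character) echoing
#'   the scalar generator parameters.
#'
#' @seealso [writeTruthTable()], [readTruthTable()]
#' @exportClass SimTruth
setClass("SimTruth", representation(
  markers = "data.frame",
  modules = "data.frame",
  params = "data.frame"
))

#' Per-(gene, tissue) tissue-association results
#'
#' Result container of [callAssociations()]: one record per gene and tissue
#' holding the one-vs-rest Wilcoxon p-value, fold change, LDA ROC AUC, and
#' the composite pass flag, together with the thresholds that defined it.
#'
#' @slot table data.frame with columns `gene`, `tissue`, `p_value`,
#'   `fold_change`, `lda_auc`, `passes`.
#' @slot criteria List with elements `pMax`, `fcMin`, `aucMin`,
#'   `pseudocount` (see [associationCriteria()]).
#'
#' @seealso [callAssociations()], [assocTable()], [passingGenes()]
#' @exportClass TissueAssociation
setClass("TissueAssociation", representation(
  table = "data.frame",
  criteria = "list"
))

setValidity("TissueAssociation", function(object) {
  tab <- object@table
  need <- c("gene", "tissue", "p_value", "fold_change", "lda_auc", "passes")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (any(tab$lda_auc < 0 | tab$lda_auc > 1, na.rm = TRUE))
      return("lda_auc must lie in [0, 1]")
    cfg <- object@criteria
    expect <- tab$p_value < cfg$pMax & tab$fold_change >= cfg$fcMin &
      tab$lda_auc >= cfg$aucMin
    if (!identical(as.logical(tab$passes), as.logical(expect)))
      return("pass flags inconsistent with stored statistics and criteria")
  }
  TRUE
})

#' Co-expression module partition
#'
#' Result of [detectModules()] (and [mergeModules()]): a gene-to-module
#' labelling with the reserved label `"unassigned"` for genes in no module,
#' module eigengenes (unit-norm first principal components, one row per
#' module), and the detection/merge provenance.
#'
#' @slot labels Named character vector, gene -> module label.
#' @slot eigengenes Numeric matrix, modules x samples, rows unit-norm.
#' @slot mergeHistory data.frame recording iterative eigengene merges
#'   (columns `from`, `into`, `dissimilarity`).
#' @slot power Soft-threshold power used for the adjacency.
#' @slot cutHeight Height at which the average-linkage tree was cut.
#'
#' @seealso [detectModules()], [moduleLabels()], [moduleEigengenes()]
#' @exportClass CoexpressionModules
setClass("CoexpressionModules", representation(
  labels = "character",
  eigengenes = "matrix",
  mergeHistory = "data.frame",
  power = "numeric",
  cutHeight = "numeric"
))

setValidity("CoexpressionModules", function(object) {
  mods <- setdiff(unique(object@labels), "unassigned")
  if (length(mods) && nrow(object@eigengenes) &&
      !all(mods %in% rownames(object@eigengenes)))
    return("every module must have an eigengene row")
  TRUE
})

#' Maximum-mutual-information network
#'
#' Result of [c3netNetwork()]: the undirected edge set obtained by letting
#' every gene keep only the edge to its maximal-MI significant neighbour,
#' plus the connected-component decomposition of the resulting graph.
#'
#' @slot edges data.frame with columns `gene1`, `gene2`, `mi` (gene1 < gene2).
#' @slot membership Named integer vector, gene -> component id.
#' @slot threshold MI significance threshold that was applied.
#'
#' @seealso [c3netNetwork()], [miEdges()], [subnetworkOf()]
#' @exportClass MINetwork
setClass("MINetwork", representation(
  edges = "data.frame",
  membership = "integer",
  threshold = "numeric"
))

setValidity("MINetwork", function(object) {
  n <- length(object@membership)
  if (nrow(object@edges) > n)
    return("edge count cannot exceed gene count (one pick per gene)")
  if (nrow(object@edges) &&
      !all(c(object@edges$gene1, object@edges$gene2) %in%
             names(object@membership)))
    return("edges reference unknown genes")
  TRUE
})
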