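#' Module containing the focal genes
#'
#' Returns the module holding the plurality of the focal genes (e.g. the
#' tissue-associated receptor genes whose context is being characterized).
#' A tie between modules is an error listing the candidates, as is a focal
#' set that is entirely unassigned.
#'
#' @param modules A [CoexpressionModules-class].
#' @param focalGenes Character vector of genes present in the partition.
#' @return The module label.
#' @export
focalModule <- function(modules, focalGenes) {
  labels <- moduleLabels(modules)
  missing <- setdiff(focalGenes, names(labels))
  if (length(missing))
    stop("focal genes absent from the partition: ",
         paste(missing, collapse = ", "))
  lab <- labels[focalGenes]
  lab <- lab[lab != "unassigned"]
  if (!length(lab))
    stop("all focal genes are unassigned")
  counts <- sort(table(lab), decreasing = TRUE)
  top <- names(counts)[counts == counts[1L]]
  if (length(top) > 1L)
    stop("focal genes tie between modules: ",
         paste(sort(top), collapse = ", "))
  top
}

#' Assemble a pipeline configuration
#'
#' Collects the stage parameters of [runPipeline()] with the package
#' defaults. Either a `SimSpec` (self-contained synthetic run) or paths to
#' an expression GCT and metadata TSV must be supplied.
#'
#' @param simSpec Optional [SimSpec-class] to simulate inputs from.
#' @param exprPath,metaPath Optional GCT / metadata TSV paths (used when
#'   `simSpec` is `NULL`).
#' @param gmtPath Optional GMT annotation path; when absent the enrichment
#'   stage is skipped with a warning.
#' @param outDir Output directory (created if needed).
#' @param focalTissue Tissue whose samples feed the co-expression network;
#'   default: the first tissue with a passing gene.
#' @param focalGenes Genes locating the focal module; default: the passing
#'   genes of the focal tissue.
#' @param criteria [associationCriteria()] list.
#' @param minSamplesPerTissue Tissue filter threshold (default 1 so small
#'   synthetic designs keep every tissue; use 100 for atlas-scale data).
#' @param minDetectedFrac Detection filter as a fraction of the network
#'   sample count (default 0.5, mirroring a 650-of-1305 filter).
#' @param power Optional explicit soft-threshold power; when `NULL` the
#'   power is fitted with [pickSoftPower()].
#' @param powers,r2Target Soft-threshold search space and fit target.
#' @param minModuleSize,cutHeightFrac,kmeMin,mergeHeight Module detection
#'   and merge parameters.
#' @param tomCutoff TOM edge export cutoff (default 0.025).
#' @param miAlpha,miPermutations MI significance parameters.
#' @param qMax,minOverlap Enrichment reporting thresholds.
#' @param seed Global seed.
#' @return A named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(simSpec = NULL, exprPath = NULL, metaPath = NULL,
                           gmtPath = NULL, outDir = tempfile("orAtlas_run_"),
                           focalTissue = NULL, focalGenes = NULL,
                           criteria = associationCriteria(),
                           minSamplesPerTissue = 1L,
                           minDetectedFrac = 0.5,
                           power = NULL, powers = 1:20, r2Target = 0.8,
                           minModuleSize = 30L, cutHeightFrac = 0.99,
                           kmeMin = 0.5, mergeHeight = 0.25,
                           tomCutoff = 0.025,
                           miAlpha = 0.01, miPermutations = 100L,
                           qMax = 0.05, minOverlap = 10L, seed = 42L) {
  if (is.null(simSpec) && (is.null(exprPath) || is.null(metaPath)))
    stop("either simSpec or exprPath + metaPath must be given")
  as.list(environment())
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: (optional) synthetic-data
#' generation, tissue-association calling, co-expression network and
#' module detection on the focal tissue, identification of the module
#' containing the focal genes, maximal-MI sub-network segmentation of that
#' module, and term enrichment. Stage outputs are written as TSV/GCT/SIF
#' files under `config$outDir` together with a machine-readable JSON run
#' report (stage counts, parameters, file inventory).
#'
#' @param config Output of [pipelineConfig()].
#' @return The run report, invisibly (a named list; also written as
#'   `report.json`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  echoFields <- c("minSamplesPerTissue", "minDetectedFrac", "power",
                  "r2Target", "minModuleSize", "cutHeightFrac", "kmeMin",
                  "mergeHeight", "tomCutoff", "miAlpha", "miPermutations",
                  "qMax", "minOverlap")
  report <- list(seed = config$seed,
                 parameters = c(config[echoFields], config$criteria),
                 stages = list(), outputs = character())
  out <- function(name) file.path(config$outDir, name)

  # -- inputs ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simSpec)) {
    sim <- simulateTissueExperiment(config$simSpec, seed = config$seed)
    se <- sim$se
    truth <- sim$truth
    writeGCT(se, out("expression.gct"))
    utils::write.table(
      data.frame(sample_id = colnames(se),
                 tissue = colData(se)$tissue),
      out("metadata.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeTruthTable(truth, out("truth.tsv"))
    report$stages$simulate <- list(
      genes = nrow(se), samples = ncol(se),
      tissues = length(unique(colData(se)$tissue)),
      markers = nrow(truthMarkers(truth)))
  } else {
    se <- readGCT(config$exprPath)
    annot <- readSampleMetadata(config$metaPath)
    annot <- annot[intersect(colnames(se), rownames(annot)), ,
                   drop = FALSE]
    se <- se[, rownames(annot)]
    SummarizedExperiment::colData(se)$tissue <- annot$tissue
  }
  annot <- colData(se)
  if (config$minSamplesPerTissue > 1L) {
    annot <- filterTissues(annot, config$minSamplesPerTissue)
    se <- se[, rownames(annot)]
  }

  # -- tissue association --------------------------------------------
  assoc <- callAssociations(se, criteria = config$criteria)
  tab <- assocTable(assoc)
  utils::write.table(tab, out("associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  z <- tissueZscore(se)
  utils::write.table(data.frame(gene = rownames(z), z,
                                check.names = FALSE),
                     out("tissue_zscore.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$stages$assoc <- list(
    records = nrow(tab),
    passing_genes = length(passingGenes(assoc)),
    passing_tissues = length(passingTissues(assoc)))
  if (!is.null(truth)) {
    rec <- markerRecovery(assoc, truth)
    report$stages$assoc$sensitivity <- rec$sensitivity
    report$stages$assoc$specificity <- rec$specificity
  }

  # -- co-expression network on the focal tissue ---------------------
  focalTissue <- config$focalTissue
  if (is.null(focalTissue)) {
    pt <- passingTissues(assoc)
    if (!length(pt)) stop("assoc stage found no passing tissue; ",
                          "set focalTissue explicitly")
    focalTissue <- sort(pt)[1L]
  }
  nFocal <- sum(colData(se)$tissue == focalTissue)
  logexpr <- preprocessExpression(
    se, tissues = focalTissue,
    minDetectedSamples = ceiling(config$minDetectedFrac * nFocal))
  usedPower <- config$power
  if (is.null(usedPower)) {
    sft <- pickSoftPower(logexpr, powers = config$powers,
                         r2Target = config$r2Target)
    usedPower <- sft$power
  }
  adj <- signedAdjacency(logexpr, usedPower)
  tom <- tomSimilarity(adj)
  modules <- detectModules(tom, logexpr,
                           minModuleSize = config$minModuleSize,
                           cutHeightFrac = config$cutHeightFrac,
                           kmeMin = config$kmeMin, power = usedPower)
  modules <- mergeModules(modules, logexpr, config$mergeHeight)
  utils::write.table(
    data.frame(gene = names(moduleLabels(modules)),
               module = moduleLabels(modules)),
    out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  eg <- moduleEigengenes(modules)
  if (nrow(eg))
    utils::write.table(data.frame(module = rownames(eg), eg,
                                  check.names = FALSE),
                       out("eigengenes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edges <- exportTOMEdges(tom, config$tomCutoff)
  utils::write.table(edges, out("tom_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeSIF(edges, out("tom_edges.sif"), relation = "tom")
  report$stages$network <- list(
    focal_tissue = focalTissue, power = usedPower,
    genes = nrow(logexpr), modules = length(moduleSizes(modules)),
    tom_edges = nrow(edges))

  # -- focal module + MI sub-networks --------------------------------
  focalGenes <- config$focalGenes
  if (is.null(focalGenes)) {
    pg <- tab$gene[tab$passes & tab$tissue == focalTissue]
    focalGenes <- intersect(pg, names(moduleLabels(modules)))
  }
  focal <- focalModule(modules, focalGenes)
  moduleGenes <- names(moduleLabels(modules))[
    moduleLabels(modules) == focal]
  miExpr <- logexpr[moduleGenes, , drop = FALSE]
  thr <- miThreshold(miExpr, nPermutations = config$miPermutations,
                     alpha = config$miAlpha, seed = config$seed)
  net <- c3netNetwork(miMatrix(miExpr), threshold = thr)
  utils::write.table(miEdges(net), out("c3net_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeSIF(miEdges(net), out("c3net_edges.sif"), relation = "mi")
  utils::write.table(
    data.frame(gene = names(net@membership), component = net@membership),
    out("c3net_components.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$stages$c3net <- list(
    focal_module = focal, module_genes = length(moduleGenes),
    threshold = thr, edges = nrow(miEdges(net)),
    largest_component = max(componentSizes(net)))

  # -- enrichment ----------------------------------------------------
  if (!is.null(config$gmtPath) && file.exists(config$gmtPath)) {
    annotation <- readGMT(config$gmtPath)
    enr <- enrichHypergeometric(moduleGenes, annotation,
                                universe = rownames(logexpr),
                                qMax = config$qMax,
                                minOverlap = config$minOverlap)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$enrich <- list(terms_tested = nrow(enr),
                                 terms_passing = sum(enr$passes))
  } else {
    if (!is.null(config$gmtPath))
      warning("GMT file not found; enrichment stage skipped")
    report$stages$enrich <- list(skipped = TRUE)
  }

  report$outputs <- list.files(config$outDir)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}

#' Score marker recovery against a truth table
#'
#' Compares the passing (gene, tissue) pairs of a [TissueAssociation-class]
#' with the planted markers of a [SimTruth-class].
#'
#' @param assoc A `TissueAssociation`.
#' @param truth A `SimTruth`.
#' @return List with `sensitivity` (planted pairs recovered), `specificity`
#'   (non-planted pairs correctly not called), and the counts behind them.
#' @export
markerRecovery <- function(assoc, truth) {
  tab <- assocTable(assoc)
  planted <- paste(truthMarkers(truth)$gene, truthMarkers(truth)$tissue)
  called <- paste(tab$gene, tab$tissue)[tab$passes]
  isPlanted <- paste(tab$gene, tab$tissue) %in% planted
  tp <- sum(tab$passes & isPlanted)
  fp <- sum(tab$passes & !isPlanted)
  fn <- sum(!tab$passes & isPlanted)
  tn <- sum(!tab$passes & !isPlanted)
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       truePositives = tp, falsePositives = fp,
       falseNegatives = fn, trueNegatives = tn,
       called = called)
}
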