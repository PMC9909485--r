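#' Construct a synthetic-experiment specification
#'
#' Builds a [SimSpec-class] describing the generative model of
#' [simulateTissueExperiment()]. Per gene \eqn{g} and sample \eqn{s} of
#' tissue \eqn{t}, the latent log10 expression is
#' \deqn{\ell = \mu_g + \sum_m \lambda_{g,m} z_{m,s} + \varepsilon,}
#' with \eqn{\mu_g \sim N(}`baselineLog10Mean`, `baselineLog10Sd`\eqn{)},
#' module factors \eqn{z_{m,s} \sim N(0, f_m)} shared by all genes of module
#' \eqn{m}, and \eqn{\varepsilon \sim N(0,}`noiseSdLog10`\eqn{)}. If
#' \eqn{(g,t)} is a planted marker, \eqn{\ell} gains
#' \eqn{\log_{10}(\mathrm{fold})}. TPM is \eqn{10^\ell}, zeroed with the
#' gene's dropout probability — except in a marker gene's own target tissue,
#' so the planted fold change is realized.
#'
#' @param tissues Tissue labels, or an integer count (labels are generated).
#' @param samplesPerTissue Integer scalar or per-tissue vector.
#' @param genes Gene symbols, or an integer count.
#' @param baselineLog10Mean,baselineLog10Sd Baseline log10-TPM distribution
#'   across genes (defaults 0 and 0.5).
#' @param noiseSdLog10 Per-measurement log10 noise sd (default 0.3).
#' @param dropoutProb Scalar or per-gene dropout probability in \[0, 1\].
#' @param markers `NULL` or a data.frame with columns `gene`, `tissue`,
#'   `fold` (fold > 1).
#' @param modules `NULL` or a data.frame with columns `gene`, `module`,
#'   `loading` (loading in (0, 1\]).
#' @param moduleFactorSd Named per-module factor sd (default 1 for every
#'   module named in `modules`).
#' @param seed Integer seed (default 1).
#' @return A validated `SimSpec`.
#' @seealso [demoSimSpec()] for the bundled demonstration conditions.
#' @export
SimSpec <- function(tissues, samplesPerTissue, genes,
                    baselineLog10Mean = 0, baselineLog10Sd = 0.5,
                    noiseSdLog10 = 0.3, dropoutProb = 0,
                    markers = NULL, modules = NULL, moduleFactorSd = NULL,
                    seed = 1L) {
  if (is.numeric(tissues) && length(tissues) == 1L)
    tissues <- sprintf("tissue%02d", seq_len(tissues))
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("GENE%04d", seq_len(genes))
  samplesPerTissue <- as.integer(rep_len(samplesPerTissue, length(tissues)))
  names(samplesPerTissue) <- tissues
  dropoutProb <- rep_len(dropoutProb, length(genes))
  names(dropoutProb) <- genes
  if (is.null(markers))
    markers <- data.frame(gene = character(), tissue = character(),
                          fold = numeric())
  if (is.null(modules))
    modules <- data.frame(gene = character(), module = character(),
                          loading = numeric())
  if (is.null(moduleFactorSd)) {
    mods <- unique(modules$module)
    moduleFactorSd <- stats::setNames(rep(1, length(mods)), mods)
  }
  new("SimSpec", tissues = tissues, samplesPerTissue = samplesPerTissue,
      genes = genes, baselineLog10Mean = baselineLog10Mean,
      baselineLog10Sd = baselineLog10Sd, noiseSdLog10 = noiseSdLog10,
      dropoutProb = dropoutProb, markers = markers, modules = modules,
      moduleFactorSd = moduleFactorSd, seed = as.integer(seed))
}

#' Bundled demonstration conditions
#'
#' The package's reference synthetic conditions: a multi-tissue design with
#' receptor-like sparsely expressed genes (OR-style symbols, dropout 0.6),
#' a subset of which are planted as tissue markers at a large fold change,
#' assigned round-robin across tissues. Defaults: 10 tissues x 100 samples,
#' 20 markers at fold 50, 380 null receptor-like genes, seed 42.
#'
#' @param nTissues,samplesPerTissue Design size.
#' @param nMarkers,markerFold Planted markers and their TPM fold change.
#' @param nNullOR Receptor-like genes with no planted signal.
#' @param dropoutProb Dropout probability of the receptor-like genes.
#' @param modules,moduleFactorSd Optional planted co-expression modules
#'   (passed through to [SimSpec()]); module genes get ordinary symbols and
#'   no dropout.
#' @param seed Integer seed (default 42).
#' @return A `SimSpec`.
#' @export
demoSimSpec <- function(nTissues = 10L, samplesPerTissue = 100L,
                        nMarkers = 20L, markerFold = 50,
                        nNullOR = 380L, dropoutProb = 0.6,
                        modules = NULL, moduleFactorSd = NULL,
                        seed = 42L) {
  tissues <- sprintf("tissue%02d", seq_len(nTissues))
  orGenes <- sprintf("OR%dZ%d", seq_len(nMarkers + nNullOR),
                     rep(1:9, length.out = nMarkers + nNullOR))
  genes <- orGenes
  drop <- stats::setNames(rep(dropoutProb, length(orGenes)), orGenes)
  if (!is.null(modules)) {
    genes <- c(genes, modules$gene)
    drop <- c(drop, stats::setNames(rep(0, nrow(modules)), modules$gene))
  }
  markers <- data.frame(
    gene = orGenes[seq_len(nMarkers)],
    tissue = rep(tissues, length.out = nMarkers),
    fold = markerFold
  )
  SimSpec(tissues = tissues, samplesPerTissue = samplesPerTissue,
          genes = genes, dropoutProb = drop, markers = markers,
          modules = modules, moduleFactorSd = moduleFactorSd, seed = seed)
}

#' Generate a synthetic multi-tissue TPM experiment
#'
#' Draws a TPM matrix, sample annotation and ground-truth table from the
#' generative model in a [SimSpec-class] (see [SimSpec()] for the model).
#' Deterministic given the seed: each model component (baselines, factors,
#' noise, dropout) draws from its own seed derived from the global one.
#'
#' @param spec A `SimSpec`.
#' @param seed Optional integer overriding `spec@seed`.
#' @return A list with elements `se` (a `SummarizedExperiment` with assay
#'   `tpm`, `colData(.)$tissue`, and per-gene generator annotations in
#'   `rowData`) and `truth` (a [SimTruth-class]).
#' @examples
#' sim <- simulateTissueExperiment(demoSimSpec(nTissues = 3,
#'   samplesPerTissue = 10, nMarkers = 3, nNullOR = 20))
#' sim$se
#' sim$truth
#' @export
simulateTissueExperiment <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SimSpec"))
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  seed <- as.integer(seed) %% .Machine$integer.max

  genes <- spec@genes
  tissues <- spec@tissues
  nG <- length(genes)
  tissueOf <- rep(tissues, times = spec@samplesPerTissue)
  nS <- length(tissueOf)
  sampleIds <- sprintf("S%05d", seq_len(nS))

  set.seed(seed)
  mu <- stats::rnorm(nG, spec@baselineLog10Mean, spec@baselineLog10Sd)
  names(mu) <- genes
  L <- matrix(mu, nG, nS, dimnames = list(genes, sampleIds))

  set.seed(seed + 1L)
  if (nrow(spec@modules)) {
    for (m in unique(spec@modules$module)) {
      rows <- spec@modules[spec@modules$module == m, ]
      z <- stats::rnorm(nS, 0, spec@moduleFactorSd[[m]])
      L[rows$gene, ] <- L[rows$gene, , drop = FALSE] +
        outer(rows$loading, z)
    }
  }

  set.seed(seed + 2L)
  if (spec@noiseSdLog10 > 0)
    L <- L + matrix(stats::rnorm(nG * nS, 0, spec@noiseSdLog10), nG, nS)

  markerOf <- stats::setNames(rep(NA_character_, nG), genes)
  if (nrow(spec@markers)) {
    for (i in seq_len(nrow(spec@markers))) {
      g <- spec@markers$gene[i]
      t <- spec@markers$tissue[i]
      L[g, tissueOf == t] <- L[g, tissueOf == t] +
        log10(spec@markers$fold[i])
      markerOf[g] <- t
    }
  }

  tpm <- 10^L

  set.seed(seed + 3L)
  for (g in genes) {
    p <- spec@dropoutProb[[g]]
    if (p <= 0) next
    mask <- stats::runif(nS) < p
    if (!is.na(markerOf[[g]]))
      mask[tissueOf == markerOf[[g]]] <- FALSE  # planted signal survives
    tpm[g, mask] <- 0
  }

  moduleOf <- stats::setNames(rep(NA_character_, nG), genes)
  if (nrow(spec@modules))
    moduleOf[spec@modules$gene] <- spec@modules$module

  se <- SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(tissue = tissueOf,
                                   row.names = sampleIds),
    rowData = S4Vectors::DataFrame(
      baseline_log10_mean = mu,
      dropout_prob = spec@dropoutProb,
      marker_tissue = markerOf,
      module = moduleOf,
      row.names = genes
    )
  )
  truth <- new("SimTruth",
    markers = spec@markers,
    modules = spec@modules[, c("gene", "module"), drop = FALSE],
    params = data.frame(
      key = c("n_tissues", "n_samples", "n_genes", "baseline_log10_mean",
              "baseline_log10_sd", "noise_sd_log10", "seed"),
      value = as.character(c(length(tissues), nS, nG,
                             spec@baselineLog10Mean, spec@baselineLog10Sd,
                             spec@noiseSdLog10, seed)),
      stringsAsFactors = FALSE
    ))
  list(se = se, truth = truth)
}

#' Write / read a ground-truth table
#'
#' Serializes a [SimTruth-class] to a sectioned TSV (`marker`, `module` and
#' `param` rows) that round-trips losslessly.
#'
#' @param truth A `SimTruth`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `SimTruth` (reader).
#' @export
writeTruthTable <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("section\tfield1\tfield2\tfield3", con)
  m <- truth@markers
  if (nrow(m))
    writeLines(paste("marker", m$gene, m$tissue,
                     formatC(m$fold, format = "g", digits = 15),
                     sep = "\t"), con)
  mm <- truth@modules
  if (nrow(mm))
    writeLines(paste("module", mm$gene, mm$module, "", sep = "\t"), con)
  p <- truth@params
  if (nrow(p))
    writeLines(paste("param", p$key, p$value, "", sep = "\t"), con)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  mk <- tab[tab$section == "marker", , drop = FALSE]
  md <- tab[tab$section == "module", , drop = FALSE]
  pr <- tab[tab$section == "param", , drop = FALSE]
  new("SimTruth",
      markers = data.frame(gene = mk$field1, tissue = mk$field2,
                           fold = as.numeric(mk$field3),
                           stringsAsFactors = FALSE),
      modules = data.frame(gene = md$field1, module = md$field2,
                           stringsAsFactors = FALSE),
      params = data.frame(key = pr$field1, value = pr$field2,
                          stringsAsFactors = FALSE))
}

#' Self-contained demonstration spec for the full pipeline
#'
#' A compact design exercising every pipeline stage: planted tissue markers
#' (receptor-like symbols), two planted co-expression modules in which the
#' focal tissue's markers are embedded (so the focal-module lookup, MI
#' segmentation and enrichment stages all have structure to find), plus
#' independent background genes.
#'
#' @param nTissues,samplesPerTissue Design size (defaults 4 x 60).
#' @param seed Integer seed (default 42).
#' @return A `SimSpec`.
#' @seealso [runPipeline()]
#' @export
demoPipelineSpec <- function(nTissues = 4L, samplesPerTissue = 60L,
                             seed = 42L) {
  tissues <- sprintf("tissue%02d", seq_len(nTissues))
  focalMarkers <- c("OR10Z6", "OR5Z2", "OR5Z3")
  otherMarkers <- sprintf("OR%dZ1", seq_len(nTissues - 1L))
  nullOR <- sprintf("OR%dZ9", 20 + seq_len(30))
  m1Extra <- sprintf("KRT%03d", 1:40)
  m2Genes <- sprintf("COL%03d", 1:40)
  background <- sprintf("BG%03d", 1:30)
  genes <- c(focalMarkers, otherMarkers, nullOR, m1Extra, m2Genes,
             background)
  dropout <- stats::setNames(rep(0, length(genes)), genes)
  dropout[c(focalMarkers, otherMarkers, nullOR)] <- 0.6
  markers <- data.frame(
    gene = c(focalMarkers, otherMarkers),
    tissue = c(rep(tissues[1L], 3L), tissues[-1L]),
    fold = 50)
  modules <- data.frame(
    gene = c(focalMarkers, m1Extra, m2Genes),
    module = c(rep("m1", 3L + length(m1Extra)),
               rep("m2", length(m2Genes))),
    loading = 0.9)
  SimSpec(tissues = tissues, samplesPerTissue = samplesPerTissue,
          genes = genes, noiseSdLog10 = 0.3, dropoutProb = dropout,
          markers = markers, modules = modules, seed = seed)
}
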