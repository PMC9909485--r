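# orAtlas

`orAtlas` discovers genes that are highly expressed in specific tissues from
a multi-tissue bulk RNA-seq TPM matrix, and characterizes their functional
context with co-expression and mutual-information networks. The motivating
use case is an expression atlas of the olfactory receptor (OR) gene family
— large, sparsely expressed, and strongly tissue-dependent — across a
GTEx-style collection of thousands of samples from dozens of tissues, but
every step applies to any gene subset.

## What it computes

**Tissue association.** For each gene *g* and tissue *t*, the samples of
*t* are compared against all remaining samples (one-vs-rest). Gene *g* is
called *highly expressed* in *t* when all three hold:

- two-sided Wilcoxon rank-sum *p* < 10⁻¹⁰,
- fold change (mean TPM in *t* + ε) / (mean TPM elsewhere + ε) ≥ 25, with
  pseudocount ε = 10⁻⁴,
- ROC AUC of a one-feature linear discriminant ≥ 0.85 (for a single
  feature this equals the Mann–Whitney AUC up to orientation).

A per-tissue z-score matrix of median expression supports heatmap-style
summaries (`tissueZscore()`).

**Co-expression modules.** Within a focal tissue, genes detected in enough
samples are log-transformed (log₁₀(TPM + 10⁻⁴)) and a weighted network is
built: signed adjacency *a_ij* = ((1 + cor(x_i, x_j))/2)^β, soft power β
fitted by scale-free topology (`pickSoftPower()`), and topological overlap

    TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij).

Modules come from average-linkage clustering of 1 − TOM with a static cut,
a minimum size, and an eigengene-membership (kME) cleanup; close modules
are merged by eigengene correlation, and edges above a TOM cutoff (default
0.025) are exportable as SIF/TSV for network viewers.

**Maximal-MI sub-networks.** Within one module, every gene keeps only the
edge to its maximal-mutual-information partner that clears a permutation
significance threshold (the c3net selection rule, reimplemented); connected
components of the resulting graph are the sub-networks
(`c3netNetwork()`, `subnetworkOf()`).

**Enrichment.** Hypergeometric over-representation of a module against a
GMT annotation, Benjamini–Hochberg corrected, reported at q ≤ 0.05 and
overlap ≥ 10 (`enrichHypergeometric()`).

**Synthetic data.** `simulateTissueExperiment()` draws a multi-tissue TPM
matrix from a log-normal model with planted tissue markers (multiplicative
fold change), planted co-expression modules (shared latent factors), and
per-gene dropout emulating sparse OR-like expression — together with a
machine-readable truth table, so every downstream claim is testable
without any download.

## Worked example

```r
library(orAtlas)

spec  <- demoSimSpec(nTissues = 4, samplesPerTissue = 100,
                     nMarkers = 4, nNullOR = 40, seed = 5)
sim   <- simulateTissueExperiment(spec)
assoc <- callAssociations(sim$se)
assoc
#> TissueAssociation with 176 (gene, tissue) records
#>   criteria: p < 1e-10, fold change >= 25, LDA AUC >= 0.85
#>   4 genes pass in >= 1 tissue; 4 tissues have >= 1 passing gene

subset(assocTable(assoc), passes)
#>     gene   tissue  p_value fold_change lda_auc passes
#> 1  OR1Z1 tissue01 3.30e-55         124       1   TRUE
#> 6  OR2Z2 tissue02 1.49e-55         101       1   TRUE
#> 11 OR3Z3 tissue03 2.64e-56         107       1   TRUE
#> 16 OR4Z4 tissue04 1.02e-54         122       1   TRUE

markerRecovery(assoc, sim$truth)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1
```

Each planted marker (fold 50 over a dropout-0.6 background) is recovered
in exactly its target tissue: the Wilcoxon p-values are far below the
10⁻¹⁰ gate, the realized fold changes exceed 100 (dropout depresses the
rest-group mean below the baseline), and the discriminant separates the
target tissue perfectly. The 40 null receptor-like genes produce no false
calls. `runPipeline(pipelineConfig(simSpec = demoPipelineSpec(),
power = 12))` chains association calling, module detection, MI
segmentation and enrichment end to end and writes all stage outputs plus
a JSON run report.

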