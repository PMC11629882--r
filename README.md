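# evmap

Dose-response transcriptomics of cells treated with extracellular
vesicles (EVs). `evmap` is an R package for researchers asking how a
recipient cell's transcriptome responds to EVs as a function of the
producer cell source and the particle dose, and how much EV-derived
RNA the recipients actually acquire. It covers a bulk arm (controls
plus 12 EV sources × 3 doses in triplicate) and a single-cell in vivo
arm (sorted cells from an EV-injected animal, graded by their
human:mouse mapped-read ratio).

## What it computes

* **Normalization** — median-of-ratios size factors: for sample *j*,
  `sf_j = median_g ( K_gj / (prod_j K_gj)^(1/n) )` over genes positive
  in all samples, with a fallback reference for sparse matrices.
* **Differential expression** — a self-contained negative binomial
  Wald test: per gene, group means on normalized counts, pooled
  method-of-moments dispersion (variance floor at the Poisson level),
  Wald statistic on the log2 mean difference, t reference with
  calibrated effective df, Benjamini–Hochberg adjustment at 0.05.
* **Sample maps** — variable genes (mean normalized count > 6, top 500
  by log-scale variance), exact tSNE, k-nearest-neighbour graph
  (k = 25 bulk, 40 single-cell; weight 1/(1+d)) and a from-scratch
  two-level **map-equation (Infomap-style) clustering**
  `L(M) = q H(Q) + sum_m p_m H(P_m)` minimized by greedy node
  aggregation with coarse tuning and restarts.
* **Enrichment statistics** — overlap enrichment
  `|A∩B| / (|A|·|B|)` (× universe size so random sets score 1),
  cluster-versus-label enrichment matrices, relative similarity from
  pairwise DE counts, hypergeometric gene-set overrepresentation with
  control-normalized fold enrichment.
* **EV uptake** — per-source cargo gene sets (abundance > 100
  normalized counts or enrichment vs ≥ 3 other sources), removal of
  recipient-expressed genes (control mean > 1), per-dose fold changes
  with a 0.01 pseudocount, OLS slope over log10(dose) and a
  dose-dependent **deliverer** call.
* **Single-cell arm** — strict QC windows (10,000 < mouse reads <
  300,000; 500 < genes detected above two normalized counts < 3,000;
  mito ratio < 0.05), ratio groups at cutoffs 0.04/0.05/0.06, 40-NN
  mapping and pseudobulk (pools of 5–6 cells) differential expression.
* **Synthetic data** — generators for all three data kinds with
  planted ground truth (shared high-dose program, source-specific
  low-dose signatures, dose-dependent cargo delivery for four sources,
  QC-failure cells), so the whole chain is verifiable offline.

## Worked example

```r
library(evmap)

design   <- bulkDesign(seed = 1)                 # 118-sample study
delivery <- deliveryDesign(design)               # cargo + deliverer flags
sim      <- generateBulkExperiment(design, delivery = delivery)
evTx     <- generateEVTranscriptomes(delivery)

res <- runBulkPipeline(sim$experiment, evExperiment = evTx,
                       config = pipelineConfig(seed = 1))
res$summary$nClusters
#> [1] 4
round(enrichmentScores(res$doseEnrichment), 2)
#>      0   20 2000 2e+05
#> 1 11.8 0.00 0.00  0.00
#> 2  0.0 3.28 0.00  0.00
#> 3  0.0 0.00 3.28  0.00
#> 4  0.0 0.00 0.00  3.28
res$uptake$source[res$uptake$deliverer]
#> [1] "Panc1"  "HAEC"   "THP1"   "Jurkat"
```

The map-equation stage finds 4 clusters; the dose-enrichment matrix
shows each cluster aligned with one dose level (controls = dose 0;
an entry of 11.8 means that cluster/dose pair co-occurs 11.8× more
than random assignment would give, 3.28 for the 36-sample treatment
clusters), while source-group enrichment stays at chance (≈ 1). The
uptake stage flags exactly the four planted dose-dependent deliverer
EV types.

For the single-cell arm:

```r
sc  <- generateSingleCells(singleCellDesign(seed = 1))
out <- runSCPipeline(sc$experiment, sc$accounting,
                     config = pipelineConfig(seed = 1))
out$summary$nPassing   # 182 of 192 cells pass QC
out$summary$nGroups    # 4 ratio groups
```

## Package layout

S4 classes `EVExperiment` (a SummarizedExperiment of validated
counts), `DEResult`, `SampleGraph`, `GeneSetCollection` and
`EnrichmentMatrix` carry the data between stages; `runBulkPipeline()`
and `runSCPipeline()` compose them, and `inst/scripts/evmap.R` is a
thin command-line wrapper (simulate / run-bulk / run-sc). The methods
vignette (`vignettes/evmap-methods.Rmd`) documents the models,
parameter choices and limitations.
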