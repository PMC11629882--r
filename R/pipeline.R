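#' Pipeline configuration with the study's printed defaults
#'
#' Every analysis threshold with its default: DE significance 0.05,
#' variable-gene mean floor 6, 500 variable genes, 25 neighbours for
#' bulk maps and 40 for single-cell maps, EV-abundance cutoff 100,
#' recipient-expression cutoff 1, uptake pseudocount 0.01, ratio
#' cutoffs 0.04/0.05/0.06, and the QC windows. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        deAlpha = 0.05,
        varMinMean = 6,
        nVariableGenes = 500,
        kBulk = 25,
        kSingleCell = 40,
        perplexityBulk = 10,
        perplexitySingleCell = 30,
        nRestarts = 10,
        evAbundance = 100,
        expressedCutoff = 1,
        pseudocount = 0.01,
        ratioCutoffs = c(0.04, 0.05, 0.06),
        qcReadsWindow = c(10000, 300000),
        qcGenesWindow = c(500, 3000),
        qcMitoMax = 0.05,
        seed = 1)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Load a YAML pipeline configuration
#' @param path YAML file with keys from \code{\link{pipelineConfig}}.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

.writeResolvedConfig <- function(cfg, outdir) {
    if (is.null(outdir)) return(invisible(NULL))
    yaml::write_yaml(unclass(cfg), file.path(outdir, "config_resolved.yaml"))
}

#' Run the bulk EV dose-response workflow
#'
#' Normalize, select variable genes, embed (tSNE), build the 25-NN
#' graph, partition it by the map equation, score cluster enrichment
#' against dose and source group, and (when EV transcriptomes are
#' supplied) quantify dose-dependent transcript delivery per source.
#'
#' @param experiment \linkS4class{EVExperiment} with colData columns
#'   source, sourceGroup, dose, treatment.
#' @param evExperiment optional \linkS4class{EVExperiment} of EV
#'   transcriptomes for the uptake stage.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir optional directory for per-stage outputs (TSV/JSON plus
#'   the resolved configuration).
#' @return list: experiment (normalized), variableGenes, graph
#'   (clustered \linkS4class{SampleGraph}), doseEnrichment,
#'   sourceGroupEnrichment (\linkS4class{EnrichmentMatrix}), uptake
#'   (data.frame or NULL), summary (machine-readable list).
#' @export
runBulkPipeline <- function(experiment, evExperiment = NULL,
                            config = pipelineConfig(), outdir = NULL) {
    stopifnot(is(experiment, "EVExperiment"))
    md <- as.data.frame(colData(experiment))
    need <- c("source", "dose", "treatment")
    miss <- setdiff(need, names(md))
    if (length(miss))
        stop("metadata validation failed: missing column(s) ",
             paste(miss, collapse = ", "))
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)

    experiment <- normalizeCounts(experiment)
    vg <- selectVariableGenes(experiment, minMean = config$varMinMean,
                              nTop = config$nVariableGenes)
    coords <- embedTSNE(experiment, genes = vg,
                        perplexity = config$perplexityBulk,
                        seed = config$seed)
    graph <- buildKnnGraph(coords, k = config$kBulk)
    graph <- mapEquationCluster(graph, nRestarts = config$nRestarts,
                                seed = config$seed)
    part <- modulePartition(graph)
    doseLab <- stats::setNames(as.character(md$dose), rownames(md))
    doseEnr <- labelEnrichmentMatrix(part, doseLab)
    # source groups exist only for EV-treated samples
    evSamp <- rownames(md)[md$treatment == "EV"]
    grpLab <- stats::setNames(md$sourceGroup[md$treatment == "EV"], evSamp)
    grpEnr <- labelEnrichmentMatrix(part[evSamp], grpLab)

    uptake <- NULL
    if (!is.null(evExperiment))
        uptake <- uptakeProfiles(experiment, evExperiment,
                                 threshold = config$evAbundance,
                                 expressedCutoff = config$expressedCutoff,
                                 pseudocount = config$pseudocount)

    summary <- list(
        schema = "evmap/bulk-summary/1",
        seed = config$seed,
        nSamples = ncol(experiment),
        nClusters = max(part),
        codelength = graph@codelength,
        maxDoseEnrichment = max(enrichmentScores(doseEnr)),
        maxSourceGroupEnrichment = max(enrichmentScores(grpEnr)),
        deliverers = if (!is.null(uptake))
            uptake$source[uptake$deliverer] else NULL)
    if (!is.null(outdir)) {
        writeSampleGraph(graph, file.path(outdir, "bulk"))
        writeEnrichmentMatrix(doseEnr, file.path(outdir,
                                                 "enrichment_dose.tsv"))
        writeEnrichmentMatrix(grpEnr, file.path(outdir,
                                                "enrichment_sourcegroup.tsv"))
        if (!is.null(uptake))
            utils::write.table(uptake, file.path(outdir, "uptake.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        .writeResolvedConfig(config, outdir)
    }
    list(experiment = experiment, variableGenes = vg, graph = graph,
         doseEnrichment = doseEnr, sourceGroupEnrichment = grpEnr,
         uptake = uptake, summary = summary)
}

#' Run the single-cell workflow
#'
#' QC-filter the cells, assign human:mouse ratio dose groups, map the
#' passing cells (tSNE, 40-NN graph, map-equation clustering), score
#' cluster enrichment against the ratio groups, and contrast the low
#' and high groups by pseudobulk differential expression.
#'
#' @param experiment \linkS4class{EVExperiment} of cell counts.
#' @param accounting per-cell table from \code{\link{cellAccounting}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir optional output directory.
#' @return list: accounting (passing cells with group labels), graph,
#'   groupEnrichment, de (low vs high \linkS4class{DEResult} or NULL
#'   when a group is too small), summary.
#' @export
runSCPipeline <- function(experiment, accounting,
                          config = pipelineConfig(), outdir = NULL) {
    stopifnot(is(experiment, "EVExperiment"))
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    pass <- qcFilter(accounting, readsWindow = config$qcReadsWindow,
                     genesWindow = config$qcGenesWindow,
                     mitoMax = config$qcMitoMax)
    pass$group <- as.character(ratioGroups(pass,
                                           cutoffs = config$ratioCutoffs))
    sub <- experiment[, pass$cell]
    sub <- normalizeCounts(sub)
    vg <- selectVariableGenes(sub, minMean = config$varMinMean,
                              nTop = config$nVariableGenes)
    coords <- embedTSNE(sub, genes = vg,
                        perplexity = config$perplexitySingleCell,
                        seed = config$seed)
    graph <- buildKnnGraph(coords, k = config$kSingleCell)
    graph <- mapEquationCluster(graph, nRestarts = config$nRestarts,
                                seed = config$seed)
    part <- modulePartition(graph)
    grpEnr <- labelEnrichmentMatrix(part,
                                    stats::setNames(pass$group, pass$cell))
    labels <- stats::setNames(pass$group, pass$cell)
    de <- NULL
    if (sum(labels == "low") >= 10 && sum(labels == "high") >= 10)
        de <- pseudobulkDE(sub, labels, "low", "high",
                           alpha = config$deAlpha, seed = config$seed)
    summary <- list(
        schema = "evmap/sc-summary/1",
        seed = config$seed,
        nCells = nrow(accounting),
        nPassing = nrow(pass),
        nGroups = length(unique(pass$group)),
        nClusters = max(part),
        codelength = graph@codelength,
        nDELowHigh = if (!is.null(de)) length(significantGenes(de)) else NA)
    if (!is.null(outdir)) {
        writeSampleGraph(graph, file.path(outdir, "sc"))
        utils::write.table(pass, file.path(outdir, "cells_passing.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeEnrichmentMatrix(grpEnr,
                              file.path(outdir, "enrichment_ratiogroup.tsv"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        .writeResolvedConfig(config, outdir)
    }
    list(accounting = pass, graph = graph, groupEnrichment = grpEnr,
         de = de, summary = summary)
}
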