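#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- colData colData<- rowData
#' @importFrom BiocGenerics counts sizeFactors sizeFactors<-
NULL

#' EVExperiment: a validated count container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a raw
#' gene-by-sample count matrix in the \code{"counts"} assay, per-sample
#' metadata in \code{colData}, and (after \code{\link{normalizeCounts}})
#' median-of-ratios size factors plus a \code{"normcounts"} assay.
#'
#' Validity demands unique gene and sample identifiers and non-negative
#' integer raw counts; normalized values are raw counts divided by their
#' sample's size factor.
#'
#' @seealso \code{\link{EVExperiment}} the constructor,
#'   \code{\link{computeSizeFactors}}, \code{\link{normalizeCounts}}
#' @export
setClass("EVExperiment", contains = "SummarizedExperiment")

setValidity("EVExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (is.null(rownames(m)) || is.null(colnames(m)))
            msg <- c(msg, "counts must have gene rownames and sample colnames")
        else {
            if (anyDuplicated(rownames(m)))
                msg <- c(msg, sprintf("duplicate gene identifiers: %s",
                    paste(unique(rownames(m)[duplicated(rownames(m))])[1:min(3, sum(duplicated(rownames(m))))],
                          collapse = ", ")))
            if (anyDuplicated(colnames(m)))
                msg <- c(msg, "duplicate sample identifiers")
        }
        if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(m != round(m))) msg <- c(msg, "raw counts must be integers")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EVExperiment from a count matrix and sample metadata
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param metadata optional data.frame of per-sample annotation, rows
#'   aligned 1:1 with the columns of \code{counts}.
#' @return an \linkS4class{EVExperiment}.
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ev <- EVExperiment(m, data.frame(dose = c(0, 0, 20, 20)))
#' ev
#' @export
EVExperiment <- function(counts, metadata = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "numeric"
    if (is.null(metadata)) {
        cd <- DataFrame(row.names = colnames(counts))
    } else {
        if (nrow(metadata) != ncol(counts))
            stop("metadata rows (", nrow(metadata),
                 ") do not align with count columns (", ncol(counts), ")")
        cd <- DataFrame(metadata, row.names = colnames(counts))
    }
    new("EVExperiment",
        SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' @describeIn EVExperiment raw counts accessor.
#' @param object an EVExperiment.
#' @export
setMethod("counts", "EVExperiment", function(object) assay(object, "counts"))

#' DEResult: one differential-expression contrast
#'
#' Per-gene table for a two-group negative binomial Wald contrast: log2
#' fold change (A over B), Wald statistic, raw and BH-adjusted p-values
#' and an up/down direction label, together with the group definitions
#' and the significance threshold used. Genes with zero counts across
#' both groups are excluded from testing and from the BH denominator.
#'
#' @seealso \code{\link{nbWaldDE}}, \code{\link{significantGenes}}
#' @export
setClass("DEResult", representation(
    table  = "data.frame",
    groupA = "character",
    groupB = "character",
    alpha  = "numeric"))

setValidity("DEResult", function(object) {
    tb <- object@table
    need <- c("gene", "log2FoldChange", "stat", "pvalue", "padj", "direction")
    msg <- character()
    if (!all(need %in% names(tb)))
        msg <- c(msg, paste("table must contain",
                            paste(setdiff(need, names(tb)), collapse = ", ")))
    else {
        ok <- !is.na(tb$pvalue)
        if (any(tb$padj[ok] < tb$pvalue[ok] - 1e-12))
            msg <- c(msg, "adjusted p must be >= raw p")
        up <- tb$direction == "up"
        if (any(up & tb$log2FoldChange < 0, na.rm = TRUE))
            msg <- c(msg, "direction inconsistent with fold-change sign")
    }
    if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be a single value in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn DEResult the per-gene result table.
#' @param object a DEResult.
#' @export
deTable <- function(object) {
    stopifnot(is(object, "DEResult"))
    object@table
}

#' @describeIn DEResult genes with adjusted p below the stored threshold,
#'   optionally restricted by direction.
#' @param direction "any", "up" or "down".
#' @export
significantGenes <- function(object, direction = c("any", "up", "down")) {
    stopifnot(is(object, "DEResult"))
    direction <- match.arg(direction)
    tb <- object@table
    keep <- !is.na(tb$padj) & tb$padj < object@alpha
    if (direction != "any") keep <- keep & tb$direction == direction
    tb$gene[keep]
}

setMethod("show", "DEResult", function(object) {
    tb <- object@table
    nsig <- sum(!is.na(tb$padj) & tb$padj < object@alpha)
    cat("DEResult:", paste(object@groupA, collapse = "+"), "vs",
        paste(object@groupB, collapse = "+"), "\n",
        nrow(tb), "genes tested;", nsig, "significant at adjusted p <",
        object@alpha, "\n")
})

#' SampleGraph: a kNN sample/cell map with an optional module partition
#'
#' Weighted undirected graph over samples (or cells) built by linking
#' each node to its k nearest neighbours in a 2-D embedding and taking
#' the union of the directed links. Holds the embedding, the neighbour
#' count k, and after \code{\link{mapEquationCluster}} a module id per
#' node plus the final map-equation codelength.
#'
#' @seealso \code{\link{buildKnnGraph}}, \code{\link{mapEquationCluster}}
#' @export
setClass("SampleGraph", representation(
    nodes      = "character",
    edges      = "data.frame",
    embedding  = "matrix",
    k          = "integer",
    partition  = "integer",
    codelength = "numeric"))

setValidity("SampleGraph", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    e <- object@edges
    if (nrow(e)) {
        if (!all(c("from", "to", "weight") %in% names(e)))
            msg <- c(msg, "edges need columns from, to, weight")
        else {
            if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be > 0")
            if (any(e$from < 1 | e$from > length(object@nodes)) ||
                any(e$to < 1 | e$to > length(object@nodes)))
                msg <- c(msg, "edge endpoints out of range")
            if (any(e$from == e$to)) msg <- c(msg, "self loops not allowed")
        }
    }
    if (length(object@partition) &&
        length(object@partition) != length(object@nodes))
        msg <- c(msg, "partition must cover all nodes exactly once")
    if (length(msg)) msg else TRUE
})

#' @describeIn SampleGraph module assignment (named integer vector), or
#'   NULL if the graph has not been clustered yet.
#' @param object a SampleGraph.
#' @export
modulePartition <- function(object) {
    stopifnot(is(object, "SampleGraph"))
    if (!length(object@partition)) return(NULL)
    stats::setNames(object@partition, object@nodes)
}

#' @describeIn SampleGraph edge list with node identifiers resolved.
#' @export
graphEdges <- function(object) {
    stopifnot(is(object, "SampleGraph"))
    e <- object@edges
    data.frame(from = object@nodes[e$from], to = object@nodes[e$to],
               weight = e$weight)
}

#' @describeIn SampleGraph the 2-D embedding coordinates.
#' @export
graphEmbedding <- function(object) {
    stopifnot(is(object, "SampleGraph"))
    object@embedding
}

setMethod("show", "SampleGraph", function(object) {
    cat("SampleGraph:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges (k =", object@k, ")\n")
    if (length(object@partition))
        cat("  partition:", max(object@partition), "modules, codelength",
            round(object@codelength, 4), "bits\n")
})

#' GeneSetCollection: named gene sets over a fixed universe
#'
#' Container for annotation terms or differential-expression gene sets.
#' Every set must be a subset of the universe and the universe must be
#' non-empty.
#'
#' @seealso \code{\link{readGMT}}, \code{\link{genesetOverrepresentation}}
#' @export
setClass("GeneSetCollection", representation(
    universe = "character",
    sets     = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (!length(object@universe)) msg <- c(msg, "universe must be non-empty")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "duplicate genes in universe")
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || any(names(object@sets) == ""))
            msg <- c(msg, "all sets must be named")
        out <- vapply(object@sets,
                      function(s) sum(!(s %in% object@universe)), 0L)
        if (any(out > 0))
            msg <- c(msg, sprintf("set '%s' has %d genes outside the universe",
                                  names(object@sets)[which(out > 0)[1]],
                                  out[which(out > 0)[1]]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param universe character vector of all gene identifiers under
#'   consideration.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, universe) {
    new("GeneSetCollection", universe = as.character(universe),
        sets = lapply(sets, as.character))
}

#' @describeIn GeneSetCollection the named list of sets.
#' @param object a GeneSetCollection.
#' @export
geneSets <- function(object) {
    stopifnot(is(object, "GeneSetCollection"))
    object@sets
}

#' @describeIn GeneSetCollection the gene universe.
#' @export
geneUniverse <- function(object) {
    stopifnot(is(object, "GeneSetCollection"))
    object@universe
}

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
        length(object@universe), "genes\n")
})

#' EnrichmentMatrix: overlap-enrichment scores between two labelings
#'
#' Cross-tabulation of two set systems over the same objects (for
#' example map-equation clusters against treatment doses), scored by the
#' overlap-enrichment statistic: overlap divided by the product of the
#' two set sizes, reported both raw and multiplied by the universe size
#' so the expectation under random labels is 1.
#'
#' @seealso \code{\link{labelEnrichmentMatrix}},
#'   \code{\link{overlapEnrichment}}
#' @export
setClass("EnrichmentMatrix", representation(
    scores       = "matrix",
    raw          = "matrix",
    overlap      = "matrix",
    rowSizes     = "integer",
    colSizes     = "integer",
    universeSize = "integer"))

setValidity("EnrichmentMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@scores), dim(object@overlap)))
        msg <- c(msg, "scores and overlap dimensions differ")
    mins <- outer(object@rowSizes, object@colSizes, pmin)
    if (any(object@overlap > mins))
        msg <- c(msg, "overlap exceeds min of the two set sizes")
    if (any(object@scores < 0)) msg <- c(msg, "scores must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentMatrix normalized scores (null expectation 1).
#' @param object an EnrichmentMatrix.
#' @export
enrichmentScores <- function(object) {
    stopifnot(is(object, "EnrichmentMatrix"))
    object@scores
}

#' @describeIn EnrichmentMatrix raw overlap counts.
#' @export
enrichmentOverlap <- function(object) {
    stopifnot(is(object, "EnrichmentMatrix"))
    object@overlap
}

setMethod("show", "EnrichmentMatrix", function(object) {
    cat("EnrichmentMatrix:", nrow(object@scores), "x", ncol(object@scores),
        "over", object@universeSize, "objects\n")
    print(round(object@scores, 3))
})
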