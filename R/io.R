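#' Read a count matrix
#'
#' Two dialects: \code{"tsv"}, a dense gene x sample table with a header
#' row of sample identifiers and gene identifiers in the first column;
#' \code{"mtx"}, a matrix-market triplet with plain-text gene and sample
#' sidecar files (one identifier per line). Duplicate identifiers and
#' (for raw matrices) non-integer values are rejected.
#'
#' @param path the TSV or MTX file.
#' @param dialect "tsv" or "mtx".
#' @param genesPath,samplesPath sidecar paths for the mtx dialect
#'   (defaults: genes.txt / samples.txt next to the matrix).
#' @param raw validate values as raw integer counts (default TRUE).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path, dialect = c("tsv", "mtx"),
                       genesPath = file.path(dirname(path), "genes.txt"),
                       samplesPath = file.path(dirname(path), "samples.txt"),
                       raw = TRUE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "tsv") {
        tb <- utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        genes <- tb[[1]]
        m <- as.matrix(tb[, -1, drop = FALSE])
        rownames(m) <- genes
    } else {
        m0 <- Matrix::readMM(path)
        genes <- readLines(genesPath)
        samples <- readLines(samplesPath)
        if (nrow(m0) != length(genes))
            stop("gene sidecar length (", length(genes),
                 ") does not match matrix rows (", nrow(m0), ")")
        if (ncol(m0) != length(samples))
            stop("sample sidecar length (", length(samples),
                 ") does not match matrix columns (", ncol(m0), ")")
        m <- as.matrix(m0)
        dimnames(m) <- list(genes, samples)
    }
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifier: ",
             rownames(m)[duplicated(rownames(m))][1])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample identifier: ",
             colnames(m)[duplicated(colnames(m))][1])
    if (!is.numeric(m)) stop("non-numeric values in count matrix")
    if (raw && any(m != round(m))) {
        bad <- which(m != round(m), arr.ind = TRUE)[1, ]
        stop("non-integer raw count at gene ", rownames(m)[bad[1]],
             ", sample ", colnames(m)[bad[2]])
    }
    storage.mode(m) <- "double"
    m
}

#' Write a count matrix
#'
#' Inverse of \code{\link{readCounts}}; write-then-read reproduces the
#' matrix exactly for integer counts.
#'
#' @param m matrix (or \linkS4class{EVExperiment}, whose raw counts are
#'   written).
#' @param path destination file.
#' @param dialect "tsv" or "mtx".
#' @param genesPath,samplesPath sidecar paths for the mtx dialect.
#' @export
writeCounts <- function(m, path, dialect = c("tsv", "mtx"),
                        genesPath = file.path(dirname(path), "genes.txt"),
                        samplesPath = file.path(dirname(path), "samples.txt")) {
    dialect <- match.arg(dialect)
    if (is(m, "EVExperiment")) m <- counts(m)
    if (dialect == "tsv") {
        tb <- data.frame(gene = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(tb, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        writeLines(rownames(m), genesPath)
        writeLines(colnames(m), samplesPath)
    }
    invisible(path)
}

#' Read sample metadata (CSV)
#'
#' @param path CSV with a \code{sample} column; remaining columns are
#'   free-form annotation.
#' @return data.frame with samples as rownames.
#' @export
readMetadata <- function(path) {
    md <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"sample" %in% names(md))
        stop("metadata needs a 'sample' column")
    if (anyDuplicated(md$sample))
        stop("duplicate sample in metadata: ",
             md$sample[duplicated(md$sample)][1])
    rownames(md) <- md$sample
    md
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description,
#' then genes.
#'
#' @param path GMT file.
#' @param universe optional gene universe; defaults to the union of all
#'   sets.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, universe = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3)
    if (length(short))
        stop("malformed GMT line ", short[1], ": fewer than 3 fields")
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, "", 1)
    if (is.null(universe)) universe <- unique(unlist(sets))
    GeneSetCollection(sets, universe)
}

#' Write gene sets to a GMT file
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path destination.
#' @param descriptions optional per-set description column.
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
    sets <- geneSets(collection)
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), ""), path)
    invisible(path)
}

#' Write an enrichment matrix as TSV
#' @param em an \linkS4class{EnrichmentMatrix}.
#' @param path destination.
#' @export
writeEnrichmentMatrix <- function(em, path) {
    stopifnot(is(em, "EnrichmentMatrix"))
    tb <- data.frame(cluster = rownames(enrichmentScores(em)),
                     enrichmentScores(em), check.names = FALSE)
    utils::write.table(tb, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a SampleGraph (partition, edges, embedding) as TSV files
#' @param graph a \linkS4class{SampleGraph}.
#' @param prefix file-name prefix; writes <prefix>_partition.tsv,
#'   <prefix>_edges.tsv, <prefix>_embedding.tsv.
#' @export
writeSampleGraph <- function(graph, prefix) {
    stopifnot(is(graph, "SampleGraph"))
    if (length(graph@partition)) {
        utils::write.table(
            data.frame(node = graph@nodes, module = graph@partition),
            paste0(prefix, "_partition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    utils::write.table(graphEdges(graph), paste0(prefix, "_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(node = rownames(graph@embedding), graph@embedding),
        paste0(prefix, "_embedding.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(prefix)
}
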