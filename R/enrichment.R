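#' Overlap enrichment between two object sets
#'
#' The study's set-association statistic: the overlap divided by the
#' product of the two set sizes. The raw score is multiplied by the
#' universe size to give the normalized score, whose expectation under
#' random sets is 1 (fold over random expectation). Symmetric in the two
#' sets.
#'
#' @param setA,setB character vectors of object (sample/gene)
#'   identifiers; must be non-empty.
#' @param universeSize number of objects in the universe.
#' @return list with \code{raw} (overlap / (nA * nB)), \code{score}
#'   (raw * universeSize) and \code{overlap}.
#' @examples
#' overlapEnrichment(letters[1:10], letters[1:10], 100)$score  # 10
#' @export
overlapEnrichment <- function(setA, setB, universeSize) {
    if (!length(setA)) stop("setA is empty")
    if (!length(setB)) stop("setB is empty")
    ov <- length(intersect(setA, setB))
    raw <- ov / (length(unique(setA)) * length(unique(setB)))
    list(raw = raw, score = raw * universeSize, overlap = ov)
}

#' Overlap-enrichment matrix between a partition and a labelling
#'
#' Applies \code{\link{overlapEnrichment}} to every (module, label) pair
#' of object sets, with the universe being all objects carrying both
#' assignments.
#'
#' @param partition named vector (e.g. module ids from
#'   \code{\link{modulePartition}}).
#' @param labels named vector of labels over the same objects.
#' @return an \linkS4class{EnrichmentMatrix} (rows = partition classes,
#'   columns = label classes).
#' @export
labelEnrichmentMatrix <- function(partition, labels) {
    if (is.null(names(partition)) || is.null(names(labels)))
        stop("partition and labels must be named by object")
    if (!setequal(names(partition), names(labels)))
        stop("partition and labels cover different objects")
    labels <- labels[names(partition)]
    objs <- names(partition)
    rows <- split(objs, partition)
    cols <- split(objs, as.character(labels))
    N <- length(objs)
    score <- raw <- matrix(0, length(rows), length(cols),
                           dimnames = list(names(rows), names(cols)))
    ov <- matrix(0L, length(rows), length(cols),
                 dimnames = dimnames(score))
    for (i in seq_along(rows)) for (j in seq_along(cols)) {
        e <- overlapEnrichment(rows[[i]], cols[[j]], N)
        score[i, j] <- e$score; raw[i, j] <- e$raw; ov[i, j] <- e$overlap
    }
    new("EnrichmentMatrix", scores = score, raw = raw, overlap = ov,
        rowSizes = lengths(rows), colSizes = lengths(cols),
        universeSize = as.integer(N))
}

#' Relative similarity from pairwise DE counts
#'
#' Converts a symmetric matrix of significantly-differentially-expressed
#' gene counts between groups into a similarity: each directed count is
#' scaled by the row group's average DE count against all partners
#' (e_ij = d_ij / mean_k d_ik), the two directed ratios are averaged,
#' and the similarity is the inverse — few DE genes between two groups
#' relative to their usual separation means high similarity. A zero DE
#' count maps to \code{cap}.
#'
#' @param d symmetric numeric matrix of DE counts, zero diagonal.
#' @param cap similarity assigned when the scaled distance is 0
#'   (default 100).
#' @return symmetric similarity matrix (diagonal \code{cap}); the
#'   directed ratios are attached as attribute \code{"directed"}.
#' @export
relativeSimilarity <- function(d, cap = 100) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
        stop("d must be a symmetric square matrix")
    if (any(diag(d) != 0)) stop("d must have a zero diagonal")
    if (nrow(d) < 3) stop("relative similarity needs >= 3 groups")
    n <- nrow(d)
    a <- rowSums(d) / (n - 1)                   # average DE vs partners
    if (all(a == 0)) {
        warning("all pairwise DE counts are zero; similarity undefined, ",
                "returning cap")
        out <- matrix(cap, n, n, dimnames = dimnames(d))
        return(out)
    }
    e <- sweep(d, 1, ifelse(a > 0, a, NA), "/")  # e_ij = d_ij / a_i
    m <- (e + t(e)) / 2
    sim <- ifelse(is.na(m) | m == 0, cap, 1 / m)
    diag(sim) <- cap
    dimnames(sim) <- dimnames(d)
    attr(sim, "directed") <- e
    sim
}

#' Hypergeometric gene-set overrepresentation
#'
#' One-sided hypergeometric tail test of each term against a query gene
#' list, with fold enrichment (overlap / query size) / (term size /
#' universe size) and BH adjustment across terms.
#'
#' @param query character vector of genes, all inside the collection's
#'   universe.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return data.frame: term, termSize, overlap, fold, pvalue, padj.
#' @export
genesetOverrepresentation <- function(query, collection) {
    stopifnot(is(collection, "GeneSetCollection"))
    query <- unique(query)
    uni <- geneUniverse(collection)
    out <- setdiff(query, uni)
    if (length(out))
        stop("query genes outside the universe: ",
             paste(utils::head(out, 5), collapse = ", "))
    N <- length(uni); q <- length(query)
    sets <- geneSets(collection)
    ov <- vapply(sets, function(s) length(intersect(s, query)), 0L)
    sz <- lengths(sets)
    fold <- (ov / q) / (sz / N)
    p <- stats::phyper(ov - 1, sz, N - sz, q, lower.tail = FALSE)
    data.frame(term = names(sets), termSize = sz, overlap = ov,
               fold = fold, pvalue = p, padj = bhAdjust(p),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Control-normalized fold enrichment
#'
#' Divides each term's fold enrichment in a group by the fold of the
#' same term in the control result (computed from the union of all
#' groups' genes against the same collection). Terms with control fold 0
#' are reported as NA (undefined), never infinite.
#'
#' @param groupResult,controlResult data.frames from
#'   \code{\link{genesetOverrepresentation}} over identical term sets.
#' @return the group result with an extra column \code{normFold}.
#' @export
controlNormalizedFold <- function(groupResult, controlResult) {
    if (!identical(groupResult$term, controlResult$term))
        stop("group and control results cover different terms")
    ctrl <- controlResult$fold
    groupResult$normFold <- ifelse(ctrl > 0, groupResult$fold / ctrl, NA_real_)
    groupResult
}

#' Genes regulated by at least a minimum number of EV types
#'
#' Counts, across a list of per-source DE results, how many sources
#' significantly regulate each gene in a given direction and returns the
#' genes reaching the threshold (default: at least 5 EV types).
#'
#' @param deList named list of \linkS4class{DEResult}, one per EV
#'   source.
#' @param direction "up" or "down".
#' @param minTypes minimum number of sources (default 5).
#' @return character vector of recurrently regulated genes.
#' @export
recurrentDEGenes <- function(deList, direction = c("up", "down"),
                             minTypes = 5) {
    direction <- match.arg(direction)
    hits <- table(unlist(lapply(deList, significantGenes,
                                direction = direction)))
    names(hits)[hits >= minTypes]
}
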