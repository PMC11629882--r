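#' Select highly variable genes from a normalized matrix
#'
#' Restricts to genes whose mean normalized count is strictly above
#' \code{minMean}, ranks by the variance of log2(normalized + 1) and
#' returns the top \code{nTop}. Ties keep the original gene order
#' (stable ranking).
#'
#' @param object \linkS4class{EVExperiment} or normalized matrix.
#' @param minMean expression floor on the mean normalized count
#'   (default 6, strict inequality).
#' @param nTop number of genes to return (default 500).
#' @return character vector of gene identifiers, most variable first.
#' @export
selectVariableGenes <- function(object, minMean = 6, nTop = 500) {
    x <- if (is(object, "EVExperiment")) normalizedCounts(object)
         else as.matrix(object)
    keep <- rowMeans(x) > minMean
    if (!any(keep))
        stop("no gene has mean normalized count above ", minMean)
    x <- x[keep, , drop = FALSE]
    v <- apply(log2(x + 1), 1, stats::var)
    ord <- order(-v)                        # stable for ties
    rownames(x)[utils::head(ord, nTop)]
}

#' tSNE embedding of samples on selected genes
#'
#' Embeds samples in 2-D by tSNE on log2(normalized + 1) expression of
#' the selected genes, with PCA pre-reduction to at most
#' \code{initialDims} components. Exact (theta = 0) and deterministic
#' for a fixed seed.
#'
#' @param object \linkS4class{EVExperiment} or normalized matrix.
#' @param genes gene identifiers to use (default: all rows).
#' @param perplexity tSNE perplexity; requires n samples > 3 *
#'   perplexity.
#' @param seed integer seed.
#' @param initialDims PCA components kept before tSNE when the feature
#'   count exceeds them (default 50).
#' @return n x 2 coordinate matrix with sample rownames.
#' @export
embedTSNE <- function(object, genes = NULL, perplexity = 10, seed = 1,
                      initialDims = 50) {
    x <- if (is(object, "EVExperiment")) normalizedCounts(object)
         else as.matrix(object)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(x))
        if (length(miss))
            stop("unknown genes: ", paste(utils::head(miss, 3), collapse = ", "))
        x <- x[genes, , drop = FALSE]
    }
    n <- ncol(x)
    if (n <= 3 * perplexity)
        stop("perplexity ", perplexity, " infeasible for ", n,
             " samples; maximum feasible is ", floor((n - 1) / 3))
    feat <- t(log2(x + 1))
    set.seed(seed)
    out <- Rtsne::Rtsne(feat, dims = 2, perplexity = perplexity,
                        theta = 0, pca = ncol(feat) > initialDims,
                        initial_dims = initialDims,
                        check_duplicates = FALSE, verbose = FALSE)
    coords <- out$Y
    rownames(coords) <- colnames(x)
    colnames(coords) <- c("tSNE1", "tSNE2")
    coords
}

#' Build the k-nearest-neighbour sample graph
#'
#' Links every node to its k nearest Euclidean neighbours in the
#' embedding, symmetrizes by union and weights each undirected edge
#' 1 / (1 + distance). Deterministic given the coordinates (distance
#' ties broken by node order).
#'
#' @param coords n x 2 (or n x d) coordinate matrix with rownames.
#' @param k neighbours per node; must be < n.
#' @return a \linkS4class{SampleGraph}.
#' @export
buildKnnGraph <- function(coords, k) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (k >= n) stop("k (", k, ") must be smaller than the number of nodes (",
                     n, ")")
    if (k < 1) stop("k must be >= 1")
    if (is.null(rownames(coords)))
        rownames(coords) <- sprintf("node_%d", seq_len(n))
    d <- as.matrix(stats::dist(coords))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        nb <- order(d[i, -i])       # stable; indices into the reduced vector
        nb <- setdiff(seq_len(n), i)[nb][seq_len(k)]
        adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)             # union symmetrization
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = idx[, 1], to = idx[, 2],
                        weight = 1 / (1 + d[idx]))
    new("SampleGraph", nodes = rownames(coords), edges = edges,
        embedding = coords, k = as.integer(k),
        partition = integer(0), codelength = NA_real_)
}

#' Convert a SampleGraph to an igraph object
#' @param graph a \linkS4class{SampleGraph}.
#' @return an igraph undirected weighted graph.
#' @export
asIgraph <- function(graph) {
    stopifnot(is(graph, "SampleGraph"))
    g <- igraph::make_empty_graph(n = length(graph@nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = graph@nodes)
    if (nrow(graph@edges))
        g <- igraph::add_edges(g, rbind(graph@edges$from, graph@edges$to),
                               weight = graph@edges$weight)
    g
}

#' Force-directed layout for visualisation
#'
#' Fruchterman-Reingold spring layout (via igraph), deterministic per
#' seed. Purely cosmetic: no statistic in the package consumes these
#' positions.
#'
#' @param graph a \linkS4class{SampleGraph}.
#' @param seed integer seed.
#' @return n x 2 position matrix with node rownames.
#' @export
layoutForceDirected <- function(graph, seed = 1) {
    stopifnot(is(graph, "SampleGraph"))
    n <- length(graph@nodes)
    if (n == 1)
        return(matrix(0, 1, 2, dimnames = list(graph@nodes, c("x", "y"))))
    set.seed(seed)
    pos <- igraph::layout_with_fr(asIgraph(graph), niter = 1000)
    dimnames(pos) <- list(graph@nodes, c("x", "y"))
    pos
}
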