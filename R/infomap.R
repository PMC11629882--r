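# Two-level map equation minimization by greedy node aggregation.
#
# Flow model: stationary distribution of the undirected weighted random
# walk, p_i = strength_i / (2 * total edge weight). Codelength of a hard
# partition M:
#   L(M) = plogp(Q) - 2 sum_m plogp(q_m) - sum_i plogp(p_i)
#        + sum_m plogp(q_m + p_m)
# with q_m the exit flow of module m, Q = sum q_m, p_m the flow inside,
# and plogp(x) = x log2 x. Search: repeated sweeps moving single nodes
# (or aggregated modules) to neighbouring modules when the move strictly
# lowers L, alternated with module-level aggregation and a coarse-tuning
# phase that re-splits each module on its induced subgraph, restarted
# from several seeded node orders; the lowest-codelength partition wins.

.plogp <- function(x) ifelse(x > 0, x * log2(x), 0)

# Greedy local moving. nbr/wgt: adjacency lists (self-links excluded),
# p: flow per (super)node, totW: flow normalizer of the ORIGINAL graph
# (sum of node strengths there), order: sweep order, init: starting
# module per node (default singletons). Returns compacted module ids.
.greedyMove <- function(nbr, wgt, p, totW, order, init = NULL) {
    n <- length(p)
    strength <- vapply(seq_len(n), function(i) sum(wgt[[i]]), 0)
    module <- if (is.null(init)) seq_len(n) else as.integer(init)
    k <- max(module)
    pm <- as.numeric(rowsum(p, module, reorder = TRUE))
    wout <- numeric(k)
    for (i in seq_len(n)) {
        cross <- module[nbr[[i]]] != module[i]
        wout[module[i]] <- wout[module[i]] + sum(wgt[[i]][cross])
    }
    if (totW == 0) return(module)
    repeat {
        improved <- FALSE
        for (i in order) {
            m <- module[i]
            nb <- nbr[[i]]
            if (!length(nb)) next
            targets <- unique(module[nb])
            targets <- targets[targets != m]
            if (!length(targets)) next
            wim <- sum(wgt[[i]][module[nb] == m])
            Q0 <- sum(wout) / totW
            bestDelta <- -1e-12; bestT <- 0L
            for (t in targets) {
                wit <- sum(wgt[[i]][module[nb] == t])
                qm0 <- wout[m] / totW; qt0 <- wout[t] / totW
                qm1 <- (wout[m] - strength[i] + 2 * wim) / totW
                qt1 <- (wout[t] + strength[i] - 2 * wit) / totW
                pm1 <- pm[m] - p[i]; pt1 <- pm[t] + p[i]
                dQ <- (qm1 + qt1) - (qm0 + qt0)
                delta <- .plogp(Q0 + dQ) - .plogp(Q0) -
                    2 * (.plogp(qm1) + .plogp(qt1) -
                         .plogp(qm0) - .plogp(qt0)) +
                    .plogp(qm1 + pm1) + .plogp(qt1 + pt1) -
                    .plogp(qm0 + pm[m]) - .plogp(qt0 + pm[t])
                if (delta < bestDelta) { bestDelta <- delta; bestT <- t }
            }
            if (bestT > 0L) {
                t <- bestT
                wit <- sum(wgt[[i]][module[nb] == t])
                wout[m] <- wout[m] - strength[i] + 2 * wim
                wout[t] <- wout[t] + strength[i] - 2 * wit
                pm[m] <- pm[m] - p[i]; pm[t] <- pm[t] + p[i]
                module[i] <- t
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    match(module, unique(module))
}

# collapse a partition to a module-level graph (self-links dropped;
# p summed per module)
.aggregate <- function(nbr, wgt, p, module) {
    k <- max(module)
    W <- matrix(0, k, k)
    for (i in seq_along(p)) {
        mi <- module[i]
        nb <- nbr[[i]]
        for (e in seq_along(nb)) {
            j <- nb[e]
            if (j > i && module[j] != mi)
                W[mi, module[j]] <- W[mi, module[j]] + wgt[[i]][e]
        }
    }
    W <- W + t(W)
    nbrA <- vector("list", k); wgtA <- vector("list", k)
    for (m in seq_len(k)) {
        nb <- which(W[m, ] > 0)
        nbrA[[m]] <- nb
        wgtA[[m]] <- W[m, nb]
    }
    list(nbr = nbrA, wgt = wgtA,
         p = as.numeric(rowsum(p, module, reorder = TRUE)))
}

# repeated module-level merging until no merge lowers L
.aggregationRounds <- function(nbr, wgt, p, totW, module) {
    repeat {
        k <- max(module)
        if (k <= 1) break
        agg <- .aggregate(nbr, wgt, p, module)
        sup <- .greedyMove(agg$nbr, agg$wgt, agg$p, totW, seq_len(k))
        if (max(sup) == k) break
        module <- match(sup[module], unique(sup[module]))
    }
    module
}

# coarse tuning: re-partition each module on its induced subgraph,
# then let aggregation recombine the submodules
.coarseTune <- function(nbr, wgt, p, totW, module) {
    sub <- integer(length(p))
    nsub <- 0L
    for (m in seq_len(max(module))) {
        idx <- which(module == m)
        if (length(idx) == 1) {
            sub[idx] <- nsub + 1L
            nsub <- nsub + 1L
            next
        }
        pos <- match(seq_along(p), idx)        # global -> local
        nbrS <- vector("list", length(idx))
        wgtS <- vector("list", length(idx))
        for (li in seq_along(idx)) {
            i <- idx[li]
            keep <- module[nbr[[i]]] == m
            nbrS[[li]] <- pos[nbr[[i]][keep]]
            wgtS[[li]] <- wgt[[i]][keep]
        }
        lab <- .greedyMove(nbrS, wgtS, p[idx], totW, seq_along(idx))
        sub[idx] <- nsub + lab
        nsub <- nsub + max(lab)
    }
    .aggregationRounds(nbr, wgt, p, totW, match(sub, unique(sub)))
}

.partitionL <- function(nbr, wgt, p, totW, module) {
    if (totW == 0) return(-sum(.plogp(p)))
    k <- max(module)
    pm <- as.numeric(rowsum(p, module, reorder = TRUE))
    wout <- numeric(k)
    for (i in seq_along(p)) {
        cross <- module[nbr[[i]]] != module[i]
        wout[module[i]] <- wout[module[i]] + sum(wgt[[i]][cross])
    }
    qm <- wout / totW
    Q <- sum(qm)
    .plogp(Q) - 2 * sum(.plogp(qm)) - sum(.plogp(p)) +
        sum(.plogp(qm + pm))
}

# one full search from a seeded node order
.mapeqOnce <- function(nbr, wgt, p, totW, rngOrder) {
    module <- .greedyMove(nbr, wgt, p, totW, rngOrder)
    module <- .aggregationRounds(nbr, wgt, p, totW, module)
    L <- .partitionL(nbr, wgt, p, totW, module)
    for (iter in 1:20) {
        cand <- .coarseTune(nbr, wgt, p, totW, module)
        Lc <- .partitionL(nbr, wgt, p, totW, cand)
        if (Lc < L - 1e-12) { module <- cand; L <- Lc } else break
    }
    list(module = module, L = L)
}

.adjacency <- function(nodes, edges) {
    n <- length(nodes)
    nbr <- rep(list(integer(0)), n)
    wgt <- rep(list(numeric(0)), n)
    for (r in seq_len(nrow(edges))) {
        a <- edges$from[r]; b <- edges$to[r]; w <- edges$weight[r]
        nbr[[a]] <- c(nbr[[a]], b); wgt[[a]] <- c(wgt[[a]], w)
        nbr[[b]] <- c(nbr[[b]], a); wgt[[b]] <- c(wgt[[b]], w)
    }
    list(nbr = nbr, wgt = wgt)
}

#' Two-level map-equation (Infomap-style) clustering
#'
#' Partitions a \linkS4class{SampleGraph} by minimizing the two-level
#' map equation over hard partitions, where node flow is the stationary
#' distribution of the weighted random walk. The search is greedy node
#' aggregation — repeated single-node moves to neighbouring modules,
#' module-level merges, and a coarse-tuning phase that re-splits each
#' module on its induced subgraph — restarted from \code{nRestarts}
#' seeded random node orders; the partition with the lowest codelength
#' wins, ties going to the first found. Accepted moves strictly decrease
#' the codelength, so the final codelength never exceeds that of the
#' all-singletons partition.
#'
#' @param graph a \linkS4class{SampleGraph}.
#' @param nRestarts number of random-order restarts (default 10).
#' @param seed integer seed for the restart orders.
#' @return the graph with \code{partition} (module ids, 1-based, in
#'   order of first appearance) and \code{codelength} filled in; a graph
#'   without edges gets every node in its own module, with a warning.
#' @export
mapEquationCluster <- function(graph, nRestarts = 10, seed = 1) {
    stopifnot(is(graph, "SampleGraph"))
    n <- length(graph@nodes)
    if (!nrow(graph@edges)) {
        warning("graph has no edges; every node is its own module")
        graph@partition <- seq_len(n)
        graph@codelength <- 0
        return(graph)
    }
    adj <- .adjacency(graph@nodes, graph@edges)
    strength <- vapply(seq_len(n), function(i) sum(adj$wgt[[i]]), 0)
    totW <- sum(strength)
    p <- strength / totW

    best <- NULL; bestL <- Inf
    set.seed(seed)
    for (r in seq_len(nRestarts)) {
        ord <- sample.int(n)
        run <- .mapeqOnce(adj$nbr, adj$wgt, p, totW, ord)
        if (run$L < bestL - 1e-12) { bestL <- run$L; best <- run$module }
    }
    graph@partition <- match(best, unique(best))
    graph@codelength <- bestL
    graph
}

#' Codelength of an arbitrary partition of a SampleGraph
#'
#' Evaluates the two-level map equation for a user-supplied partition;
#' used for verification and for comparing alternative partitions.
#'
#' @param graph a \linkS4class{SampleGraph}.
#' @param partition integer module ids, one per node.
#' @return codelength in bits.
#' @export
partitionCodelength <- function(graph, partition) {
    stopifnot(is(graph, "SampleGraph"),
              length(partition) == length(graph@nodes))
    if (!nrow(graph@edges)) return(0)
    adj <- .adjacency(graph@nodes, graph@edges)
    n <- length(graph@nodes)
    strength <- vapply(seq_len(n), function(i) sum(adj$wgt[[i]]), 0)
    totW <- sum(strength)
    .partitionL(adj$nbr, adj$wgt, strength / totW, totW,
                as.integer(match(partition, unique(partition))))
}
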