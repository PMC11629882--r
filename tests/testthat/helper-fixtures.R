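# shared fixture builders (all data generated in code)

randomCountMatrix <- function(nGenes, nSamples, mu = 50, disp = 0.1,
                              seed = 1) {
    set.seed(seed)
    matrix(rnbinom(nGenes * nSamples, mu = mu, size = 1 / disp),
           nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

# brute-force median-of-ratios oracle, written independently of the
# package implementation
bruteSizeFactors <- function(m) {
    ref <- which(apply(m, 1, function(r) all(r > 0)))
    geo <- vapply(ref, function(g) prod(m[g, ])^(1 / ncol(m)), 0)
    vapply(seq_len(ncol(m)), function(j) median(m[ref, j] / geo), 0)
}

# two tight, well-separated point clouds
twoBlobCoords <- function(n1 = 5, n2 = 5, sep = 10, seed = 1) {
    set.seed(seed)
    co <- rbind(cbind(rnorm(n1, 0, 0.1), rnorm(n1, 0, 0.1)),
                cbind(rnorm(n2, sep, 0.1), rnorm(n2, sep, 0.1)))
    rownames(co) <- sprintf("n%02d", seq_len(n1 + n2))
    co
}

# planted k-block graph as a SampleGraph (blocks of equal size)
plantedBlockGraph <- function(nBlocks = 4, blockSize = 15, pIn = 0.8,
                              pOut = 0.02, seed = 1) {
    set.seed(seed)
    n <- nBlocks * blockSize
    labels <- rep(seq_len(nBlocks), each = blockSize)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        p <- if (labels[i] == labels[j]) pIn else pOut
        if (runif(1) < p) { from <- c(from, i); to <- c(to, j) }
    }
    g <- new("SampleGraph",
             nodes = sprintf("v%02d", seq_len(n)),
             edges = data.frame(from = from, to = to, weight = 1),
             embedding = matrix(0, n, 2), k = 1L,
             partition = integer(0), codelength = NA_real_)
    list(graph = g, labels = labels)
}

adjustedRandIndex <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    expct <- si * sj / choose(sum(tab), 2)
    mx <- (si + sj) / 2
    (sij - expct) / (mx - expct)
}

# small accounting table straddling each QC window
qcEdgeTable <- function() {
    data.frame(
        cell = sprintf("c%d", 1:8),
        mouseReads   = c(10000, 10001, 299999, 300000, 50000, 50000, 50000, 50000),
        humanReads   = rep(1000, 8),
        mitoReads    = c(rep(500, 4), 500, 500, 2500, 2499),
        mitoRatio    = c(rep(0.01, 4), 0.01, 0.01, 0.05, 0.04999),
        genesDetected = c(rep(1500, 4), 500, 501, 1500, 1500),
        ratio = rep(0.02, 8))
}
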