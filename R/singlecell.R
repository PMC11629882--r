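#' Per-cell read accounting
#'
#' Assembles the per-cell table the single-cell QC consumes: mouse,
#' human and mitochondrial mapped-read totals, the mitochondrial read
#' ratio, the number of genes detected above two normalized counts, and
#' the human:mouse ratio. Normalization for the detected-genes metric
#' uses median-of-ratios size factors whose reference is built from the
#' cells passing a pre-filter of more than \code{prefilterReads} mouse
#' reads.
#'
#' @param counts gene x cell count matrix.
#' @param mouseReads,humanReads,mitoReads named per-cell read totals.
#' @param detectAbove normalized-count threshold for a gene to count as
#'   detected (default 2, strict).
#' @param prefilterReads pre-filter for the size-factor reference
#'   (default 1000 mouse reads).
#' @return data.frame: cell, mouseReads, humanReads, mitoReads,
#'   mitoRatio, genesDetected, ratio.
#' @export
cellAccounting <- function(counts, mouseReads, humanReads, mitoReads,
                           detectAbove = 2, prefilterReads = 1000) {
    counts <- as.matrix(counts)
    cells <- colnames(counts)
    for (v in c("mouseReads", "humanReads", "mitoReads")) {
        vec <- get(v)
        if (length(vec) != ncol(counts))
            stop(v, " must have one value per cell")
        if (!is.null(names(vec)) && !identical(names(vec), cells))
            stop(v, " names do not match cell identifiers")
    }
    pre <- mouseReads > prefilterReads
    if (!any(pre)) stop("no cell passes the size-factor pre-filter")
    ref <- counts[, pre, drop = FALSE]
    frac <- rowMeans(ref > 0)
    use <- frac >= 0.9
    if (!any(use)) use <- frac >= 0.5
    if (!any(use)) stop("no reference genes for cell size factors")
    lg <- log(ref[use, , drop = FALSE])
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    rat <- counts[use, , drop = FALSE] / geo
    rat[counts[use, , drop = FALSE] == 0] <- NA
    sf <- apply(rat, 2, stats::median, na.rm = TRUE)
    sf[!is.finite(sf) | sf <= 0] <- 1
    norm <- sweep(counts, 2, sf, "/")
    data.frame(cell = cells,
               mouseReads = as.numeric(mouseReads),
               humanReads = as.numeric(humanReads),
               mitoReads = as.numeric(mitoReads),
               mitoRatio = as.numeric(mitoReads) / as.numeric(mouseReads),
               genesDetected = colSums(norm > detectAbove),
               ratio = as.numeric(humanReads) / as.numeric(mouseReads),
               stringsAsFactors = FALSE)
}

#' Single-cell quality-control filter
#'
#' A cell passes when all three windows hold, every inequality strict:
#' 10,000 < mouse-mapped reads < 300,000; 500 < genes detected above two
#' normalized counts < 3,000; mitochondrial read ratio < 0.05.
#'
#' @param accounting data.frame from \code{\link{cellAccounting}}.
#' @param readsWindow,genesWindow open intervals for reads and detected
#'   genes.
#' @param mitoMax strict upper bound on the mitochondrial ratio.
#' @return the passing subset of \code{accounting}.
#' @export
qcFilter <- function(accounting, readsWindow = c(10000, 300000),
                     genesWindow = c(500, 3000), mitoMax = 0.05) {
    need <- c("cell", "mouseReads", "genesDetected", "mitoRatio")
    miss <- setdiff(need, names(accounting))
    if (length(miss))
        stop("accounting table lacks field(s): ", paste(miss, collapse = ", "))
    for (f in need[-1]) {
        bad <- which(is.na(accounting[[f]]))
        if (length(bad))
            stop("cell ", accounting$cell[bad[1]], " has missing field ", f)
    }
    pass <- accounting$mouseReads > readsWindow[1] &
        accounting$mouseReads < readsWindow[2] &
        accounting$genesDetected > genesWindow[1] &
        accounting$genesDetected < genesWindow[2] &
        accounting$mitoRatio < mitoMax
    accounting[pass, , drop = FALSE]
}

#' Human:mouse read-ratio dose groups
#'
#' Applies the printed cutoffs to the human:mouse mapped-read ratio:
#' low < 0.04 <= medium low < 0.05 <= medium high < 0.06 <= high
#' (left-closed upper intervals, so a ratio exactly at a cutoff joins
#' the higher group).
#'
#' @param x numeric ratio vector, or an accounting data.frame with
#'   humanReads and mouseReads columns.
#' @param cutoffs the three interior cutoffs (default 0.04, 0.05, 0.06).
#' @return factor with levels low, medium low, medium high, high.
#' @export
ratioGroups <- function(x, cutoffs = c(0.04, 0.05, 0.06)) {
    if (is.data.frame(x)) {
        if (any(x$mouseReads == 0))
            stop("mouse reads are zero for cell(s): ",
                 paste(utils::head(x$cell[x$mouseReads == 0], 3),
                       collapse = ", "))
        x <- x$humanReads / x$mouseReads
    }
    if (any(x < 0, na.rm = TRUE)) stop("ratios must be >= 0")
    cut(x, breaks = c(-Inf, cutoffs, Inf), right = FALSE,
        labels = c("low", "medium low", "medium high", "high"))
}

#' Pseudobulk group sizes for n cells
#'
#' Partition sizes in {5, 6} covering all n cells, maximizing the number
#' of 5-cell groups. Infeasible counts (below 10, and the gaps 13, 14
#' and 19 that no mix of fives and sixes can cover) are rejected.
#'
#' @param n cell count.
#' @return integer vector of group sizes.
#' @export
pseudobulkSizes <- function(n) {
    if (n < 10)
        stop("cannot form 2 pseudobulk groups from ", n, " cells")
    b <- n %% 5                       # minimal number of 6-cell groups
    a <- (n - 6 * b) / 5
    if (a < 0)
        stop(n, " cells cannot be partitioned into groups of 5 and 6")
    rep(c(6L, 5L), c(b, a))
}

#' Seeded random pseudobulk partition of cells
#'
#' @param cells character vector of cell identifiers.
#' @param seed integer seed.
#' @return list of cell-id vectors with sizes from
#'   \code{\link{pseudobulkSizes}}; every cell appears exactly once.
#' @export
pseudobulkPartition <- function(cells, seed = 1) {
    sizes <- pseudobulkSizes(length(cells))
    set.seed(seed)
    shuffled <- sample(cells)
    split(shuffled, rep(seq_along(sizes), sizes))
}

#' Pseudobulk differential expression between two cell groups
#'
#' Cells of each label are randomly partitioned (seeded) into pseudobulk
#' groups of 5 or 6 whose counts are summed into one column each; the
#' two labels' pseudobulks are then contrasted with
#' \code{\link{nbWaldDE}}.
#'
#' @param object \linkS4class{EVExperiment} (or count matrix) with cells
#'   as columns.
#' @param labels named label per cell.
#' @param labelA,labelB the two labels to contrast.
#' @param alpha significance threshold.
#' @param seed integer seed for the partitions.
#' @return a \linkS4class{DEResult} (groups named by pseudobulk ids).
#' @export
pseudobulkDE <- function(object, labels, labelA, labelB, alpha = 0.05,
                         seed = 1) {
    m <- if (is(object, "EVExperiment")) counts(object) else as.matrix(object)
    if (is.null(names(labels))) stop("labels must be named by cell")
    sumOne <- function(label, offset) {
        cls <- names(labels)[labels == label]
        if (length(cls) < 10)
            stop("label '", label, "' has ", length(cls),
                 " cells; at least 10 are needed for 2 pseudobulk groups")
        part <- pseudobulkPartition(cls, seed = seed + offset)
        pb <- vapply(part, function(g) rowSums(m[, g, drop = FALSE]),
                     numeric(nrow(m)))
        colnames(pb) <- sprintf("%s_pb%d", label, seq_along(part))
        pb
    }
    pbA <- sumOne(labelA, 0L)
    pbB <- sumOne(labelB, 1L)
    nbWaldDE(cbind(pbA, pbB), colnames(pbA), colnames(pbB), alpha = alpha)
}
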