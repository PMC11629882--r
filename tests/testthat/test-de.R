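test_that("BH adjustment matches the hand-enumerated step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "outside")
    expect_error(bhAdjust(c(-0.1)), "outside")
})

test_that("label permutation of identical columns gives a null result", {
    m <- randomCountMatrix(100, 3, seed = 21)
    dup <- cbind(m, m)
    colnames(dup) <- sprintf("s%02d", 1:6)
    res <- nbWaldDE(dup, colnames(dup)[1:3], colnames(dup)[4:6])
    tb <- deTable(res)
    expect_true(all(tb$log2FoldChange == 0))
    expect_length(significantGenes(res), 0)
})

test_that("swapping the groups negates fold changes, p-values unchanged", {
    m <- randomCountMatrix(300, 6, seed = 22)
    a <- colnames(m)[1:3]; b <- colnames(m)[4:6]
    r1 <- deTable(nbWaldDE(m, a, b))
    r2 <- deTable(nbWaldDE(m, b, a))
    expect_equal(r1$log2FoldChange, -r2$log2FoldChange)
    expect_equal(r1$pvalue, r2$pvalue)
    expect_equal(r1$stat, -r2$stat)
})

test_that("all-zero genes are excluded from testing and BH", {
    m <- randomCountMatrix(50, 6, seed = 23)
    m[c(3, 7), ] <- 0
    res <- nbWaldDE(m, colnames(m)[1:3], colnames(m)[4:6])
    expect_equal(nrow(deTable(res)), 48)
    expect_false(any(c("g003", "g007") %in% deTable(res)$gene))
})

test_that("group validation rejects overlap and undersized groups", {
    m <- randomCountMatrix(10, 6)
    expect_error(nbWaldDE(m, colnames(m)[1:3], colnames(m)[3:6]), "overlap")
    expect_error(nbWaldDE(m, colnames(m)[1], colnames(m)[2:4]),
                 "at least 2")
    expect_error(nbWaldDE(m, c("nope", colnames(m)[1]), colnames(m)[3:4]),
                 "unknown")
})

test_that("type-I error is calibrated under the null at 0.05 and 0.01", {
    set.seed(31)
    ng <- 6000
    mu <- exp(rnorm(ng, log(50), 1.5))
    disp <- exp(rnorm(ng, log(0.1), 0.3))
    sf <- exp(rnorm(6, 0, 0.2))
    m <- sapply(seq_len(6), function(j)
        rnbinom(ng, mu = mu * sf[j], size = 1 / disp))
    dimnames(m) <- list(sprintf("g%04d", seq_len(ng)), sprintf("s%d", 1:6))
    res <- deTable(nbWaldDE(m, paste0("s", 1:3), paste0("s", 4:6)))
    n <- nrow(res)
    for (a in c(0.05, 0.01)) {
        frac <- mean(res$pvalue < a)
        half <- 2.576 * sqrt(a * (1 - a) / n)
        expect_gt(frac, a - half)
        expect_lt(frac, a + half)
    }
})

test_that("a planted 4-fold gene is detected in almost all replicates", {
    # the planted gene is the tested gene (adjusted p = raw p for a
    # single test); size factors supplied so the 4-fold shift is not
    # absorbed into normalization
    hits <- 0
    nrep <- 200
    for (r in seq_len(nrep)) {
        set.seed(1000 + r)
        m <- matrix(c(rnbinom(3, mu = 800, size = 1 / 0.05),
                      rnbinom(3, mu = 200, size = 1 / 0.05)), 1, 6,
                    dimnames = list("g001", sprintf("s%d", 1:6)))
        res <- nbWaldDE(m, paste0("s", 1:3), paste0("s", 4:6),
                        sizeFactors = setNames(rep(1, 6), colnames(m)))
        row <- deTable(res)
        if (!is.na(row$padj) && row$padj < 0.05 && row$direction == "up")
            hits <- hits + 1
    }
    expect_gte(hits / nrep, 0.95)
})

test_that("direction of planted changes agrees with DESeq2", {
    skip_if_not_installed("DESeq2")
    set.seed(41)
    m <- matrix(rnbinom(400 * 6, mu = 100, size = 20), 400, 6)
    m[1:10, 1:3] <- matrix(rnbinom(30, mu = 600, size = 20), 10)
    m[11:20, 4:6] <- matrix(rnbinom(30, mu = 600, size = 20), 10)
    dimnames(m) <- list(sprintf("g%03d", 1:400), sprintf("s%d", 1:6))
    ours <- deTable(nbWaldDE(m, paste0("s", 1:3), paste0("s", 4:6)))
    dds <- DESeq2::DESeqDataSetFromMatrix(
        m, data.frame(g = factor(rep(c("A", "B"), each = 3))), ~g)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    ref <- DESeq2::results(dds, contrast = c("g", "A", "B"))
    planted <- sprintf("g%03d", 1:20)
    expect_equal(sign(ours$log2FoldChange[match(planted, ours$gene)]),
                 sign(ref[planted, "log2FoldChange"]))
    # planted genes found by both (ours runs without dispersion
    # shrinkage, so allow a small deficit at n = 3)
    expect_gte(sum(ours$padj[match(planted, ours$gene)] < 0.05), 15)
    expect_gte(sum(ref[planted, "padj"] < 0.05), 17)
})

test_that("pairwise DE counts are symmetric with a zero diagonal", {
    set.seed(42)
    m <- randomCountMatrix(150, 9, seed = 42)
    groups <- list(A = colnames(m)[1:3], B = colnames(m)[4:6],
                   C = colnames(m)[7:9])
    d <- pairwiseDECounts(m, groups)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0L, 3))
    expect_error(pairwiseDECounts(m, groups[1:2]), "3 groups")
})
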