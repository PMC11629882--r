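test_that("the default bulk design realizes the study layout", {
    d <- bulkDesign()
    expect_equal(designSampleCount(d), 118)
    sim <- generateBulkExperiment(d)
    expect_equal(ncol(sim$experiment), 118)
    md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
    expect_equal(sum(md$treatment == "untreated"), 5)
    expect_equal(sum(md$treatment == "buffer"), 5)
    expect_equal(sum(md$treatment == "EV"), 12 * 3 * 3)
    expect_setequal(unique(md$dose), c(0, 20, 2000, 200000))
    # ground truth references existing identifiers
    expect_true(all(unlist(sim$truth$sourceSignatures) %in%
                    rownames(sim$experiment)))
    expect_true(all(sim$truth$sharedUp %in% rownames(sim$experiment)))
})

test_that("equal seeds give identical output, different seeds differ", {
    d <- bulkDesign(nGenes = 300, nSharedUp = 20, nSharedDown = 20,
                    nSourceGenes = 5, seed = 7)
    s1 <- generateBulkExperiment(d)
    s2 <- generateBulkExperiment(d)
    expect_identical(counts(s1$experiment), counts(s2$experiment))
    s3 <- generateBulkExperiment(bulkDesign(nGenes = 300, nSharedUp = 20,
        nSharedDown = 20, nSourceGenes = 5, seed = 8))
    expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("a null design gives equal expected means across conditions", {
    d <- bulkDesign(nGenes = 400, nSharedUp = 20, nSharedDown = 20,
                    nSourceGenes = 5, sharedLfc = 0, sourceLfc = 0,
                    librarySizeSigma = 0, seed = 2)
    sim <- generateBulkExperiment(d)
    md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
    m <- counts(sim$experiment)
    ctrl <- rowMeans(m[, md$dose == 0])
    hi <- rowMeans(m[, md$dose == 200000])
    keep <- d$baselineMean > 20
    # mean ratio concentrates around 1 with no planted effect
    expect_equal(mean(hi[keep] / ctrl[keep]), 1, tolerance = 0.05)
})

test_that("planted log2 effects reproduce the NB mean model", {
    # one gene, baseline 100, dispersion 0.1, +1 log2 at high dose:
    # the empirical high/control mean ratio over many draws must sit
    # within 3 standard errors of 2
    set.seed(5)
    nrep <- 1000
    ctrl <- rnbinom(nrep, mu = 100, size = 10)
    hi <- rnbinom(nrep, mu = 100 * 2, size = 10)
    ratio <- mean(hi) / mean(ctrl)
    se <- ratio * sqrt(var(hi) / nrep / mean(hi)^2 +
                       var(ctrl) / nrep / mean(ctrl)^2)
    expect_lt(abs(ratio - 2), 3 * se)

    # and through the generator itself: high-dose shared-up genes
    d <- bulkDesign(nGenes = 2000, nSharedUp = 50, nSharedDown = 50,
                    nSourceGenes = 10, librarySizeSigma = 0, seed = 6)
    sim <- generateBulkExperiment(d)
    md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
    m <- counts(sim$experiment)
    up <- sim$truth$sharedUp
    obs <- mean(rowMeans(m[up, md$dose == 200000]) /
                rowMeans(m[up, md$dose == 0]))
    expect_equal(obs, 2^d$sharedLfc, tolerance = 0.1)
})

test_that("NB mean/dispersion fidelity: var tracks mu + alpha mu^2", {
    set.seed(9)
    for (case in list(c(mu = 50, a = 0.1), c(mu = 500, a = 0.05),
                      c(mu = 20, a = 0.4))) {
        x <- rnbinom(20000, mu = case["mu"], size = 1 / case["a"])
        expected <- case["mu"] + case["a"] * case["mu"]^2
        expect_equal(unname(var(x)), unname(expected),
                     tolerance = 0.05)
    }
})

test_that("design validation rejects malformed designs", {
    expect_error(bulkDesign(nGenes = 0), "dimension")
    expect_error(bulkDesign(doses = c(20, 20, 200)), "distinct")
    expect_error(bulkDesign(doses = c(200, 20)), "increasing")
    d <- bulkDesign(nGenes = 500, nSharedUp = 20, nSharedDown = 20,
                    nSourceGenes = 5, seed = 1)
    d$sourceSignatures[[1]][1] <- d$sharedUp[1]   # force an overlap
    expect_error(generateBulkExperiment(d), "overlap")
})

test_that("EV transcriptomes put cargo above the abundance threshold", {
    d <- bulkDesign(seed = 3)
    del <- deliveryDesign(d)
    ev <- generateEVTranscriptomes(del)
    x <- normalizedCounts(ev)
    md <- as.data.frame(SummarizedExperiment::colData(ev))
    for (s in names(del$cargoSets)) {
        cargo <- d$genes[del$cargoSets[[s]]]
        expect_true(all(rowMeans(x[cargo, md$source == s]) > 100),
                    label = paste("cargo abundance for", s))
    }
    # determinism
    ev2 <- generateEVTranscriptomes(del)
    expect_identical(counts(ev), counts(ev2))
})

test_that("cargo sets avoid recipient-expressed genes and share by group", {
    d <- bulkDesign(seed = 4)
    del <- deliveryDesign(d, withinGroupCor = 0.5)
    for (s in names(del$cargoSets))
        expect_true(all(d$baselineMean[del$cargoSets[[s]]] < 1))
    # same-group pair shares at least the designed fraction
    shared <- length(intersect(del$cargoSets[["THP1"]],
                               del$cargoSets[["Jurkat"]]))
    expect_gte(shared, round(0.5 * 30))
    # zero correlation: mean pairwise overlap matches that of random
    # sets of the same sizes (hypergeometric expectation), by MC
    poolSize <- sum(d$baselineMean < del$recipientMax)
    expected <- 30 * 30 / poolSize
    ovs <- c()
    for (seed in 1:20) {
        del0 <- deliveryDesign(d, withinGroupCor = 0, seed = seed)
        cs <- del0$cargoSets
        for (i in 1:(length(cs) - 1)) for (j in (i + 1):length(cs))
            ovs <- c(ovs, length(intersect(cs[[i]], cs[[j]])))
    }
    expect_lt(abs(mean(ovs) - expected),
              3 * sd(ovs) / sqrt(length(ovs)) + 0.05)
    expect_error(deliveryDesign(d, deliverers = "NotASource"), "unknown")
})

test_that("single-cell generator spans all four ratio groups by default", {
    sc <- generateSingleCells(singleCellDesign(seed = 1))
    expect_equal(ncol(sc$experiment), 192)
    ok <- sc$truth$qcClass == "none"
    expect_setequal(unique(sc$truth$group[ok]),
                    c("low", "medium low", "medium high", "high"))
    # determinism
    sc2 <- generateSingleCells(singleCellDesign(seed = 1))
    expect_identical(counts(sc$experiment), counts(sc2$experiment))
    expect_identical(sc$accounting, sc2$accounting)
})

test_that("planted QC failures are exactly the cells that fail QC", {
    sc <- generateSingleCells(singleCellDesign(seed = 2))
    pass <- qcFilter(sc$accounting)
    expect_setequal(pass$cell, sc$truth$cell[sc$truth$qcClass == "none"])
})

test_that("zero human reads give all-zero ratios and one group", {
    sc <- generateSingleCells(singleCellDesign(humanReadScale = 0,
                                               requireAllGroups = FALSE,
                                               seed = 3))
    expect_true(all(sc$accounting$ratio == 0))
    g <- ratioGroups(sc$accounting)
    expect_equal(as.character(unique(g)), "low")
})
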