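test_that("abundance-mode EV gene sets use a strict 100-count cutoff", {
    m <- matrix(50L, 20, 4,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("e%d", 1:4)))
    m[1:5, 1:2] <- 500L
    ev <- EVExperiment(m, data.frame(source = rep(c("A", "B"), each = 2)))
    ev <- normalizeCounts(ev, sizeFactors = rep(1, 4))
    sets <- defineEVGeneSets(ev, mode = "abundance")
    expect_setequal(sets$A, sprintf("g%02d", 1:5))
    expect_length(sets$B, 0)        # all means 50: empty set
})

test_that("enrichment mode requires >= 3 other sources and >= 4 sources", {
    set.seed(16)
    # 4 sources x 3 reps; g1 high in A vs all 3 others, g2 high in A vs
    # only 2 others (also high in D)
    m <- matrix(rnbinom(50 * 12, mu = 100, size = 20), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("e%d", 1:12)))
    src <- rep(c("A", "B", "C", "D"), each = 3)
    m[1, src == "A"] <- rnbinom(3, mu = 2000, size = 20)
    m[2, src %in% c("A", "D")] <- rnbinom(6, mu = 2000, size = 20)
    ev <- EVExperiment(m, data.frame(source = src))
    sets <- defineEVGeneSets(ev, mode = "enrichment")
    expect_true("g01" %in% sets$A)
    expect_false("g02" %in% sets$A)   # enriched vs only 2 others
    ev3 <- EVExperiment(m[, 1:9], data.frame(source = src[1:9]))
    expect_error(defineEVGeneSets(ev3, mode = "enrichment"), "at least 4")
})

test_that("recipient-expression filter is strict above 1", {
    ctrl <- matrix(c(rep(1, 4), rep(1.01, 4), rep(0, 4)), 3, 4, byrow = TRUE,
                   dimnames = list(c("gAt", "gAbove", "gZero"),
                                   sprintf("c%d", 1:4)))
    out <- filterRecipientExpressed(c("gAt", "gAbove", "gZero"), ctrl)
    expect_setequal(out, c("gAt", "gZero"))   # exactly 1.0 retained
    # brute-force scan on a random set
    set.seed(17)
    ctrl2 <- matrix(runif(200, 0, 3), 50, 4,
                    dimnames = list(sprintf("g%02d", 1:50),
                                    sprintf("c%d", 1:4)))
    keepBrute <- rownames(ctrl2)[sapply(seq_len(50), function(i)
        mean(ctrl2[i, ]) <= 1)]
    expect_setequal(filterRecipientExpressed(rownames(ctrl2), ctrl2),
                    keepBrute)
    expect_warning(filterRecipientExpressed("gAbove", ctrl), "untrackable")
})

test_that("uptake folds follow the pseudocount rules", {
    treated <- matrix(0, 2, 6, dimnames = list(c("gA", "gB"),
                                               sprintf("t%d", 1:6)))
    ctrl <- matrix(0, 2, 4, dimnames = list(c("gA", "gB"),
                                            sprintf("c%d", 1:4)))
    doses <- rep(c(20, 2000, 200000), each = 2)
    # both means zero -> fold = 0.01/0.01 = 1
    fc <- uptakeFoldChange(treated, ctrl, doses, c("gA", "gB"))
    expect_true(all(fc$perGene == 1))
    expect_true(all(fc$summary == 0))
    # treated mean 1, control 0 -> fold = 1/0.01 = 100
    treated2 <- treated; treated2["gA", ] <- 1
    fc2 <- uptakeFoldChange(treated2, ctrl, doses, c("gA", "gB"))
    expect_true(all(fc2$perGene["gA", ] == 100))
    expect_error(uptakeFoldChange(treated, ctrl, doses, character(0)),
                 "empty")
})

test_that("delivery slope matches the closed-form OLS on 3 points", {
    # summaries (0, 1, 2) at doses two decades apart -> 0.5 per decade
    sl <- deliverySlope(c(0, 1, 2), c(20, 2000, 200000))
    expect_equal(sl$slope, 0.5)
    # constant summaries -> slope 0, not a deliverer
    sl0 <- deliverySlope(c(1.3, 1.3, 1.3), c(20, 2000, 200000))
    expect_equal(sl0$slope, 0)
    expect_false(classifyDeliverer(sl0$slope, sl0$se))
    # adding a constant leaves the slope unchanged
    sl1 <- deliverySlope(c(0, 1, 2) + 7, c(20, 2000, 200000))
    expect_equal(sl1$slope, sl$slope)
    expect_error(deliverySlope(c(0, 1), c(20, 2000)), "3 dose")
})

test_that("the uptake stage recovers the planted deliverer flags", {
    d <- bulkDesign(seed = 11)
    del <- deliveryDesign(d)
    sim <- generateBulkExperiment(d, delivery = del)
    ev <- generateEVTranscriptomes(del)
    up <- uptakeProfiles(normalizeCounts(sim$experiment), ev)
    expect_setequal(up$source[up$deliverer],
                    names(del$deliverers)[del$deliverers])
    # deliverer slopes clearly positive, non-deliverers near zero
    expect_true(all(up$slope[up$deliverer] > 0.5))
    expect_true(all(abs(up$slope[!up$deliverer]) < 0.5))
})

test_that("no planted delivery yields no deliverer calls", {
    d <- bulkDesign(seed = 12)
    del <- deliveryDesign(d)
    sim <- generateBulkExperiment(d, delivery = NULL)   # nothing delivered
    ev <- generateEVTranscriptomes(del)
    up <- uptakeProfiles(normalizeCounts(sim$experiment), ev)
    expect_equal(sum(up$deliverer), 0)
    # per-dose summaries hover near zero on the log2 scale
    profs <- attr(up, "profiles")
    expect_lt(max(abs(unlist(lapply(profs, `[[`, "summary")))), 1)
})
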