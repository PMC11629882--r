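test_that("overlap enrichment follows the stated formula", {
    # identical sets of 10 in a universe of 100
    e <- overlapEnrichment(letters[1:10], letters[1:10], 100)
    expect_equal(e$raw, 0.1)
    expect_equal(e$score, 10)
    # disjoint sets
    expect_equal(overlapEnrichment(letters[1:5], letters[6:10], 100)$score, 0)
    # symmetric
    a <- letters[1:8]; b <- letters[5:20]
    expect_equal(overlapEnrichment(a, b, 50)$score,
                 overlapEnrichment(b, a, 50)$score)
    expect_error(overlapEnrichment(character(0), b, 50), "setA")
    expect_error(overlapEnrichment(a, character(0), 50), "setB")
})

test_that("normalized overlap score has null expectation 1", {
    set.seed(12)
    uni <- sprintf("g%04d", 1:1000)
    scores <- replicate(3000, {
        overlapEnrichment(sample(uni, 10), sample(uni, 20), 1000)$score
    })
    se <- sd(scores) / sqrt(length(scores))
    expect_lt(abs(mean(scores) - 1), 3.5 * se)
})

test_that("label enrichment matrix handles perfect and random agreement", {
    objs <- sprintf("o%02d", 1:40)
    part <- setNames(rep(1:4, each = 10), objs)
    same <- setNames(rep(c("w", "x", "y", "z"), each = 10), objs)
    em <- labelEnrichmentMatrix(part, same)
    sc <- enrichmentScores(em)
    expect_equal(unname(diag(sc)), rep(40 / 10, 4))
    expect_equal(sum(sc) - sum(diag(sc)), 0)
    # row overlaps sum to the cluster size when labels partition objects
    expect_equal(unname(rowSums(enrichmentOverlap(em))),
                 rep(10L, 4))
    # random labels: all entries ~1 in expectation
    set.seed(13)
    vals <- replicate(300, {
        rnd <- setNames(sample(rep(c("w", "x", "y", "z"), each = 10)), objs)
        mean(enrichmentScores(labelEnrichmentMatrix(part, rnd)))
    })
    expect_equal(mean(vals), 1, tolerance = 0.02)
    expect_error(labelEnrichmentMatrix(part, same[1:39]), "different objects")
})

test_that("relative similarity matches hand-computed ratios", {
    d <- matrix(c(0, 10, 10, 10, 0, 10, 10, 10, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    s <- relativeSimilarity(d)
    off <- s[upper.tri(s)]
    expect_true(all(abs(off - off[1]) < 1e-12))   # all equal by symmetry

    d2 <- matrix(c(0, 2, 18, 2, 0, 18, 18, 18, 0), 3,
                 dimnames = dimnames(d))
    s2 <- relativeSimilarity(d2)
    # a_A = a_B = 10, a_C = 18; e_AB = 0.2 both ways -> sim 5
    expect_equal(s2["A", "B"], 5)
    # e_AC = 1.8, e_CA = 1 -> mean 1.4 -> sim 1/1.4
    expect_equal(s2["A", "C"], 1 / 1.4)
    expect_gt(s2["A", "B"], s2["A", "C"])
    # scale invariance
    expect_equal(relativeSimilarity(10 * d2), s2, ignore_attr = TRUE)
    # degenerate: all zero -> cap with warning
    z <- matrix(0, 3, 3, dimnames = dimnames(d))
    expect_warning(sz <- relativeSimilarity(z), "undefined")
    expect_true(all(sz == 100))
    expect_error(relativeSimilarity(d2[1:2, 1:2]), "3 groups")
})

test_that("hypergeometric overrepresentation matches closed form", {
    uni <- sprintf("g%05d", 1:10000)
    term <- uni[1:20]
    gsc <- GeneSetCollection(list(hit = term, other = uni[21:120]), uni)
    res <- genesetOverrepresentation(term, gsc)
    hit <- res[res$term == "hit", ]
    expect_equal(hit$fold, (20 / 20) / (20 / 10000))   # = 500
    expect_equal(hit$pvalue, 1 / choose(10000, 20), tolerance = 1e-6)
    # empty overlap with every term
    res0 <- genesetOverrepresentation(uni[5000:5020],
                                      GeneSetCollection(list(t = term), uni))
    expect_equal(res0$fold, 0)
    expect_equal(res0$pvalue, 1)
    expect_error(genesetOverrepresentation(c("nope", uni[1]), gsc),
                 "outside the universe")
})

test_that("hypergeometric p matches brute-force enumeration (universe <= 30)", {
    # enumerate all query draws on a tiny universe and compare tail mass
    uni <- letters[1:12]
    term <- letters[1:5]
    q <- 4
    gsc <- GeneSetCollection(list(t = term), uni)
    combos <- combn(uni, q)
    for (obs in 0:4) {
        overlaps <- apply(combos, 2, function(s) length(intersect(s, term)))
        pBrute <- mean(overlaps >= obs)
        query <- c(term[seq_len(obs)],
                   setdiff(uni, term)[seq_len(q - obs)])
        p <- genesetOverrepresentation(query, gsc)$pvalue
        expect_equal(p, pBrute, tolerance = 1e-12)
    }
})

test_that("null queries give fold near 1 and uniform-ish p", {
    set.seed(14)
    uni <- sprintf("g%04d", 1:2000)
    sets <- lapply(1:20, function(i) sample(uni, 100))
    names(sets) <- paste0("t", 1:20)
    gsc <- GeneSetCollection(sets, uni)
    folds <- replicate(200, {
        mean(genesetOverrepresentation(sample(uni, 50), gsc)$fold)
    })
    expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("control-normalized folds divide by the control fold", {
    uni <- sprintf("g%04d", 1:1000)
    gsc <- GeneSetCollection(list(a = uni[1:50], b = uni[51:100]), uni)
    grp <- genesetOverrepresentation(uni[1:25], gsc)
    ctl <- genesetOverrepresentation(uni[1:25], gsc)
    same <- controlNormalizedFold(grp, ctl)
    expect_equal(same$normFold[1], 1)
    ctl2 <- ctl; ctl2$fold <- c(2, 0)
    grp2 <- grp; grp2$fold <- c(6, 3)
    out <- controlNormalizedFold(grp2, ctl2)
    expect_equal(out$normFold, c(3, NA))
    ctl3 <- ctl; ctl3$term <- rev(ctl3$term)
    expect_error(controlNormalizedFold(grp, ctl3), "different terms")
})

test_that("a planted annotation term tops the control-normalized folds", {
    set.seed(15)
    uni <- sprintf("g%04d", 1:2000)
    terms <- c(list(target = uni[1:60]),
               lapply(1:10, function(i) sample(uni, 60)))
    names(terms) <- c("target", paste0("bg", 1:10))
    gsc <- GeneSetCollection(terms, uni)
    # one source's DE genes drawn from the target term; control union
    # mixes in unrelated genes
    query <- uni[1:30]
    union <- unique(c(uni[1:30], sample(uni[500:2000], 120)))
    out <- controlNormalizedFold(genesetOverrepresentation(query, gsc),
                                 genesetOverrepresentation(union, gsc))
    expect_equal(out$term[which.max(out$normFold)], "target")
})

test_that("recurrent DE counting respects the >= 5 types rule", {
    mk <- function(genes, dirs) {
        tb <- data.frame(gene = genes, baseMeanA = 10, baseMeanB = 10,
                         log2FoldChange = ifelse(dirs == "up", 1, -1),
                         stat = 5, pvalue = 0.001, padj = 0.01,
                         direction = dirs, stringsAsFactors = FALSE)
        new("DEResult", table = tb, groupA = "a", groupB = "b",
            alpha = 0.05)
    }
    # gene gU up in 5 sources, gV up in 4
    deList <- c(lapply(1:5, function(i) mk(c("gU", "gV")[seq_len(
                    if (i <= 4) 2 else 1)], rep("up", if (i <= 4) 2 else 1))))
    expect_equal(recurrentDEGenes(deList, "up", 5), "gU")
    expect_length(recurrentDEGenes(deList, "down", 5), 0)
})
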