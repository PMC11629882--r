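#' Design of the synthetic single-cell liver experiment
#'
#' Emulates plate-sorted single cells from an EV-injected animal: each
#' cell carries a latent EV-uptake covariate realised as its
#' human:mouse mapped-read ratio (log-normal, spanning the 0.04 / 0.05 /
#' 0.06 grouping cutoffs), mouse-mapped read totals and mitochondrial
#' read fractions inside the QC windows, and two dose-linked expression
#' programs (a lysosomal-like program increasing and a
#' membrane-trafficking-like program decreasing with the latent dose).
#' A configurable number of QC-failure cells is planted per failure
#' class and labelled in the ground truth; non-planted cells are kept
#' at a safe margin inside every QC window so the planted labels are
#' exactly recoverable.
#'
#' @param nCells number of cells (default 192, one sorted plate pair).
#' @param nGenes mouse genes in the matrix (default 3200, including
#'   mitochondrial genes named with \code{mtPrefix}).
#' @param nMitoGenes,mtPrefix mitochondrial gene count and name prefix.
#' @param ratioMeanLog,ratioSdLog log-normal parameters of the
#'   human:mouse read ratio.
#' @param readsMeanLog,readsSdLog log-normal parameters of mouse-mapped
#'   read totals.
#' @param nFail named integer vector of planted failures per class
#'   (lowReads, highReads, lowGenes, highGenes, highMito).
#' @param nLyso,nMembrane,programLfc sizes and maximal log2 effect of
#'   the two dose-linked programs.
#' @param humanReadScale multiplier on human reads (0 gives an
#'   all-zero-ratio degenerate design).
#' @param requireAllGroups validate that all four ratio groups are
#'   non-empty among QC-passing cells (default TRUE).
#' @param seed integer seed.
#' @return a \code{SingleCellDesign} list.
#' @export
singleCellDesign <- function(nCells = 192, nGenes = 3200,
                             nMitoGenes = 13, mtPrefix = "mt-",
                             ratioMeanLog = log(0.045), ratioSdLog = 0.45,
                             readsMeanLog = log(8e4), readsSdLog = 0.3,
                             nFail = c(lowReads = 2, highReads = 2,
                                       lowGenes = 2, highGenes = 2,
                                       highMito = 2),
                             nLyso = 60, nMembrane = 60, programLfc = 2,
                             humanReadScale = 1,
                             requireAllGroups = TRUE,
                             seed = 1) {
    if (nCells < 4 || nGenes < 100)
        stop("singleCellDesign: degenerate dimensions")
    if (sum(nFail) >= nCells)
        stop("singleCellDesign: more planted failures than cells")
    design <- list(nCells = nCells, nGenes = nGenes,
                   nMitoGenes = nMitoGenes, mtPrefix = mtPrefix,
                   ratioMeanLog = ratioMeanLog, ratioSdLog = ratioSdLog,
                   readsMeanLog = readsMeanLog, readsSdLog = readsSdLog,
                   nFail = nFail, nLyso = nLyso, nMembrane = nMembrane,
                   programLfc = programLfc,
                   humanReadScale = humanReadScale,
                   requireAllGroups = requireAllGroups, seed = seed)
    class(design) <- "SingleCellDesign"
    design
}

#' Generate the synthetic single-cell dataset
#'
#' @param design a \code{\link{singleCellDesign}}.
#' @return list with \code{experiment} (\linkS4class{EVExperiment} of
#'   mouse gene counts), \code{accounting} (per-cell
#'   \code{\link{cellAccounting}} table) and \code{truth} (per-cell
#'   latent ratio, ratio group, planted QC class, and the program gene
#'   sets).
#' @export
generateSingleCells <- function(design) {
    stopifnot(inherits(design, "SingleCellDesign"))
    set.seed(design$seed)
    n <- design$nCells
    ng <- design$nGenes
    cells <- sprintf("cell_%03d", seq_len(n))
    mito <- sprintf("%sNd%d", design$mtPrefix, seq_len(design$nMitoGenes))
    genes <- c(mito, sprintf("Gm%04d", seq_len(ng - design$nMitoGenes)))

    # planted QC classes
    qcClass <- rep("none", n)
    slots <- sample(n, sum(design$nFail))
    qcClass[slots] <- rep(names(design$nFail), design$nFail)

    # latent uptake and read accounting
    ratio <- exp(stats::rnorm(n, design$ratioMeanLog, design$ratioSdLog)) *
        design$humanReadScale
    mouseReads <- round(exp(stats::rnorm(n, design$readsMeanLog,
                                         design$readsSdLog)))
    mouseReads <- pmin(pmax(mouseReads, 15000), 250000)   # margin in window
    mouseReads[qcClass == "lowReads"] <- 4000
    mouseReads[qcClass == "highReads"] <- 400000
    mitoFrac <- pmin(stats::rbeta(n, 6, 294), 0.04)       # margin below 0.05
    mitoFrac[qcClass == "highMito"] <- stats::runif(sum(qcClass == "highMito"),
                                                    0.10, 0.15)
    humanReads <- round(ratio * mouseReads)

    # baseline expression: housekeeping + moderately expressed + silent
    nHouse <- 200
    base <- numeric(ng)
    base[seq_len(nHouse)] <- exp(stats::rnorm(nHouse, log(60), 0.3))
    nExpr <- 2000
    exprIdx <- nHouse + seq_len(nExpr)
    base[exprIdx] <- exp(stats::rnorm(nExpr, log(8), 1))
    rest <- setdiff(seq_len(ng), c(seq_len(nHouse), exprIdx))
    base[rest] <- 0.05
    base[seq_len(design$nMitoGenes)] <- 40   # mito genes expressed

    # dose-linked programs among the moderately expressed genes
    prog <- sample(exprIdx, design$nLyso + design$nMembrane)
    lyso <- sort(prog[seq_len(design$nLyso)])
    membrane <- sort(prog[design$nLyso + seq_len(design$nMembrane)])
    s <- pmin(pmax((log(pmax(ratio, 1e-6)) - log(0.02)) /
                   (log(0.12) - log(0.02)), 0), 1)

    dispersion <- 0.3
    counts <- matrix(0, ng, n, dimnames = list(genes, cells))
    for (j in seq_len(n)) {
        mu <- base
        mu[lyso] <- mu[lyso] * 2^(design$programLfc * s[j])
        mu[membrane] <- mu[membrane] * 2^(-design$programLfc * s[j])
        if (qcClass[j] == "lowGenes") {
            keep <- c(seq_len(design$nMitoGenes), sample(exprIdx, 250))
            mu[-keep] <- 0
            mu[keep] <- pmax(mu[keep], 30)
        } else if (qcClass[j] == "highGenes") {
            mu <- pmax(mu, 20)
        }
        lib <- mouseReads[j] / 8e4
        counts[, j] <- stats::rnbinom(ng, mu = mu * lib,
                                      size = 1 / dispersion)
    }

    accounting <- cellAccounting(counts,
                                 mouseReads = stats::setNames(mouseReads, cells),
                                 humanReads = stats::setNames(humanReads, cells),
                                 mitoReads = stats::setNames(
                                     round(mitoFrac * mouseReads), cells))
    truth <- data.frame(cell = cells, ratio = ratio,
                        latentDose = s, qcClass = qcClass,
                        stringsAsFactors = FALSE)
    truth$group <- NA_character_
    ok <- truth$qcClass == "none"
    truth$group[ok] <- as.character(ratioGroups(ratio[ok]))

    if (design$requireAllGroups) {
        lv <- c("low", "medium low", "medium high", "high")
        present <- lv %in% truth$group[ok]
        if (!all(present))
            stop("ratio cutoffs not spanned: group '",
                 lv[which(!present)[1]], "' is empty at these parameters")
    }
    md <- accounting[, c("mouseReads", "humanReads", "mitoReads")]
    list(experiment = EVExperiment(counts, md),
         accounting = accounting,
         truth = truth,
         programs = list(lysosomal = genes[lyso],
                         membrane = genes[membrane]))
}
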