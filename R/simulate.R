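#' The 12 EV producer cell sources and their source groups
#'
#' The default panel: four MSC/fibroblast lines, two epithelial lines,
#' HEK293 under two growth conditions, two lines of in utero origin and
#' two immune lines.
#'
#' @return data.frame with columns \code{source} and \code{group}.
#' @export
defaultEVSources <- function() {
    data.frame(
        source = c("BJ5ta", "BM-MSC", "UCB-MSC", "WJ-MSC",
                   "HUVEC", "Panc1",
                   "HEK293T", "HEK293FS",
                   "HAEC", "CAP",
                   "THP1", "Jurkat"),
        group  = c(rep("MSC/fibroblast", 4), rep("epithelial", 2),
                   rep("HEK", 2), rep("in utero", 2), rep("immune", 2)),
        stringsAsFactors = FALSE)
}

#' Design of the synthetic bulk EV dose-response experiment
#'
#' Fixes every parameter of the bulk generator: the sample layout
#' (untreated and buffer controls plus source x dose x replicate
#' treatments), the per-gene negative binomial baseline (log-normal
#' means with a 40\% unexpressed fraction, log-normal dispersions around
#' 0.1), the shared high-dose signature (a lysosomal-like up program and
#' an exocytosis-like down program applied identically by every source
#' at the highest dose), per-source signatures active at the lowest
#' dose, the middle-dose attenuation of both, and log-normal
#' library-size variation. Signature gene sets are drawn disjointly from
#' the well-expressed genes; all draws are fixed by \code{seed}.
#'
#' @param nGenes number of genes (default 5000).
#' @param nControlsUntreated,nControlsBuffer control sample counts
#'   (defaults 5 and 5).
#' @param sources data.frame with columns source, group (default
#'   \code{\link{defaultEVSources}}).
#' @param doses ordered particle-per-cell doses (default 20, 2000,
#'   200000).
#' @param nReplicates replicates per source x dose (default 3).
#' @param exprFraction fraction of genes expressed at baseline.
#' @param baselineMeanLog,baselineMeanSdLog log-normal parameters of
#'   expressed-gene baseline means.
#' @param lowMean mean count of unexpressed genes (stray reads).
#' @param dispersionLog,dispersionSdLog log-normal parameters of the
#'   gene-wise NB dispersion.
#' @param nSharedUp,nSharedDown,sharedLfc size and log2 effect of the
#'   shared high-dose programs.
#' @param nSourceGenes,sourceLfc size and log2 effect of each source's
#'   low-dose signature.
#' @param middleAttenuation multiplier on both log2 effects at
#'   intermediate doses (default 0.5).
#' @param lowDoseSharedAttenuation multiplier on the shared program's
#'   log2 effects at the lowest dose (default 0.25): the common response
#'   is already weakly present at low dose, giving the dose gradient the
#'   sample map displays.
#' @param librarySizeSigma sd(log) of per-sample library factors.
#' @param seed integer seed fixing the whole design and generation.
#' @return a \code{BulkDesign} list.
#' @export
bulkDesign <- function(nGenes = 5000,
                       nControlsUntreated = 5, nControlsBuffer = 5,
                       sources = defaultEVSources(),
                       doses = c(20, 2000, 200000),
                       nReplicates = 3,
                       exprFraction = 0.6,
                       baselineMeanLog = log(50), baselineMeanSdLog = 1.5,
                       lowMean = 0.02,
                       dispersionLog = log(0.1), dispersionSdLog = 0.3,
                       nSharedUp = 150, nSharedDown = 150, sharedLfc = 2,
                       nSourceGenes = 50, sourceLfc = 1.5,
                       middleAttenuation = 0.5,
                       lowDoseSharedAttenuation = 0.25,
                       librarySizeSigma = 0.2,
                       seed = 1) {
    if (nGenes < 1 || nControlsUntreated < 0 || nControlsBuffer < 0 ||
        nReplicates < 1 || nrow(sources) < 1)
        stop("bulkDesign: non-positive dimension")
    if (any(doses <= 0) || anyDuplicated(doses) || is.unsorted(doses))
        stop("bulkDesign: doses must be positive, distinct and increasing")
    if (!all(c("source", "group") %in% names(sources)))
        stop("bulkDesign: sources needs columns source, group")
    if (anyDuplicated(sources$source))
        stop("bulkDesign: duplicate source labels")
    set.seed(seed)
    genes <- sprintf("G%04d", seq_len(nGenes))
    expressed <- stats::rbinom(nGenes, 1, exprFraction) == 1
    baselineMean <- ifelse(expressed,
        exp(stats::rnorm(nGenes, baselineMeanLog, baselineMeanSdLog)),
        lowMean)
    dispersion <- exp(stats::rnorm(nGenes, dispersionLog, dispersionSdLog))
    eligible <- which(expressed & baselineMean > 10)
    need <- nSharedUp + nSharedDown + nrow(sources) * nSourceGenes
    if (length(eligible) < need)
        stop("bulkDesign: not enough well-expressed genes (",
             length(eligible), ") for ", need, " signature genes")
    pick <- sample(eligible, need)
    sharedUp <- pick[seq_len(nSharedUp)]
    sharedDown <- pick[nSharedUp + seq_len(nSharedDown)]
    rest <- pick[-seq_len(nSharedUp + nSharedDown)]
    sourceSig <- split(rest, rep(seq_len(nrow(sources)), each = nSourceGenes))
    names(sourceSig) <- sources$source
    design <- list(
        nGenes = nGenes, genes = genes,
        nControlsUntreated = nControlsUntreated,
        nControlsBuffer = nControlsBuffer,
        sources = sources, doses = doses, nReplicates = nReplicates,
        baselineMean = baselineMean, dispersion = dispersion,
        sharedUp = sharedUp, sharedDown = sharedDown,
        sharedLfc = sharedLfc,
        sourceSignatures = sourceSig, sourceLfc = sourceLfc,
        middleAttenuation = middleAttenuation,
        lowDoseSharedAttenuation = lowDoseSharedAttenuation,
        librarySizeSigma = librarySizeSigma,
        seed = seed)
    class(design) <- "BulkDesign"
    validateBulkDesign(design)
    design
}

validateBulkDesign <- function(design) {
    sets <- c(list(shared_up = design$sharedUp,
                   shared_down = design$sharedDown),
              design$sourceSignatures)
    all <- unlist(sets)
    if (anyDuplicated(all))
        stop("bulkDesign: signature gene sets overlap")
    if (any(all < 1 | all > design$nGenes))
        stop("bulkDesign: signature gene index out of range")
    if (!all(is.finite(c(design$sharedLfc, design$sourceLfc))))
        stop("bulkDesign: effect sizes must be finite")
    invisible(TRUE)
}

#' Expected sample count of a bulk design
#' @param design a BulkDesign.
#' @export
designSampleCount <- function(design) {
    design$nControlsUntreated + design$nControlsBuffer +
        nrow(design$sources) * length(design$doses) * design$nReplicates
}

# per-sample log2 effect vector for one condition
.bulkLog2Fold <- function(design, source, dose) {
    lfc <- numeric(design$nGenes)
    if (is.na(source)) return(lfc)            # control
    if (!dose %in% design$doses)
        stop("unknown dose: ", dose)
    hi <- dose == max(design$doses)
    lo <- dose == min(design$doses)
    att <- if (hi || lo) 1 else design$middleAttenuation
    sig <- design$sourceSignatures[[source]]
    if (hi) {
        lfc[design$sharedUp] <- design$sharedLfc
        lfc[design$sharedDown] <- -design$sharedLfc
    } else if (lo) {
        lfc[sig] <- design$sourceLfc
        g <- design$lowDoseSharedAttenuation
        lfc[design$sharedUp] <- g * design$sharedLfc
        lfc[design$sharedDown] <- -g * design$sharedLfc
    } else {
        lfc[design$sharedUp] <- att * design$sharedLfc
        lfc[design$sharedDown] <- -att * design$sharedLfc
        lfc[sig] <- att * design$sourceLfc
    }
    lfc
}

#' Generate the synthetic bulk EV treatment experiment
#'
#' Draws negative binomial counts for every sample of the design:
#' controls at baseline, the highest dose applying the shared signature
#' identically for all sources, the lowest dose applying each source's
#' own signature, intermediate doses applying both attenuated. When a
#' \code{\link{deliveryDesign}} is supplied, EV cargo transcripts are
#' additionally planted in treated samples: deliverer sources deposit
#' cargo counts that grow linearly per decade of dose, non-deliverers
#' deposit a flat low level.
#'
#' @param design a \code{\link{bulkDesign}}.
#' @param delivery optional \code{\link{deliveryDesign}} for cargo
#'   transcript planting.
#' @return list with \code{experiment} (an \linkS4class{EVExperiment}
#'   whose colData holds source, sourceGroup, dose, replicate,
#'   treatment) and \code{truth} (signature gene names, per-sample
#'   conditions, library factors, and delivery ground truth if planted).
#' @export
generateBulkExperiment <- function(design, delivery = NULL) {
    stopifnot(inherits(design, "BulkDesign"))
    validateBulkDesign(design)
    set.seed(design$seed + 1L)
    md <- data.frame(
        sample = c(sprintf("untreated_%d", seq_len(design$nControlsUntreated)),
                   sprintf("buffer_%d", seq_len(design$nControlsBuffer))),
        source = NA_character_, sourceGroup = NA_character_,
        dose = 0, replicate = NA_integer_,
        treatment = c(rep("untreated", design$nControlsUntreated),
                      rep("buffer", design$nControlsBuffer)),
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(design$sources))) {
        for (d in design$doses) {
            md <- rbind(md, data.frame(
                sample = sprintf("%s_d%g_r%d", design$sources$source[i], d,
                                 seq_len(design$nReplicates)),
                source = design$sources$source[i],
                sourceGroup = design$sources$group[i],
                dose = d, replicate = seq_len(design$nReplicates),
                treatment = "EV", stringsAsFactors = FALSE))
        }
    }
    n <- nrow(md)
    libFactor <- exp(stats::rnorm(n, 0, design$librarySizeSigma))
    counts <- matrix(0, design$nGenes, n,
                     dimnames = list(design$genes, md$sample))
    for (j in seq_len(n)) {
        lfc <- .bulkLog2Fold(design, md$source[j], md$dose[j])
        mu <- design$baselineMean * 2^lfc * libFactor[j]
        if (!is.null(delivery) && !is.na(md$source[j])) {
            src <- md$source[j]
            cargo <- delivery$cargoSets[[src]]
            del <- if (delivery$deliverers[src])
                delivery$baseLevel + delivery$slope *
                    log10(md$dose[j] / min(design$doses))
            else delivery$nonDelivererLevel
            mu[cargo] <- mu[cargo] + del * libFactor[j]
        }
        counts[, j] <- stats::rnbinom(design$nGenes, mu = mu,
                                      size = 1 / design$dispersion)
    }
    truth <- list(
        sharedUp = design$genes[design$sharedUp],
        sharedDown = design$genes[design$sharedDown],
        sourceSignatures = lapply(design$sourceSignatures,
                                  function(i) design$genes[i]),
        conditions = md, libFactors = stats::setNames(libFactor, md$sample))
    if (!is.null(delivery)) {
        truth$cargoSets <- lapply(delivery$cargoSets,
                                  function(i) design$genes[i])
        truth$deliverers <- delivery$deliverers
    }
    list(experiment = EVExperiment(counts, md[, -1, drop = FALSE]),
         truth = truth)
}

#' Design of EV cargo transcriptomes and dose-dependent delivery
#'
#' Chooses, for each EV source, a cargo gene set from the genes the
#' recipient cells do not express (baseline mean below
#' \code{recipientMax}), with same-group sources sharing a configurable
#' fraction of their cargo (\code{withinGroupCor}); flags the deliverer
#' sources whose cargo accumulates in recipients with dose. Defaults
#' flag Panc1, HAEC, THP1 and Jurkat.
#'
#' @param bulk the \code{\link{bulkDesign}} the cargo is planted into.
#' @param cargoSize cargo genes per source (default 30).
#' @param withinGroupCor fraction of each source's cargo drawn from a
#'   shared group pool (0 = independent sets).
#' @param deliverers character vector of dose-dependent deliverer
#'   sources.
#' @param slope expected delivered normalized counts added per decade of
#'   dose for deliverers (default 8).
#' @param baseLevel delivered level at the lowest dose (default 0.5).
#' @param nonDelivererLevel flat delivered level for non-deliverers
#'   (default 1).
#' @param cargoAbundance cargo gene mean count in the EV transcriptome
#'   (default 500; downstream abundance threshold is 100).
#' @param recipientMax recipient baseline mean above which a gene is
#'   ineligible as cargo (default 0.5, below the 1-normalized-count
#'   recipient-expression cutoff).
#' @param seed integer seed.
#' @return a \code{DeliveryDesign} list.
#' @export
deliveryDesign <- function(bulk, cargoSize = 30, withinGroupCor = 0.5,
                           deliverers = c("Panc1", "HAEC", "THP1", "Jurkat"),
                           slope = 8, baseLevel = 0.5,
                           nonDelivererLevel = 1,
                           cargoAbundance = 500, recipientMax = 0.5,
                           seed = bulk$seed + 101L) {
    stopifnot(inherits(bulk, "BulkDesign"))
    if (withinGroupCor < 0 || withinGroupCor > 1)
        stop("withinGroupCor must be in [0, 1]")
    bad <- setdiff(deliverers, bulk$sources$source)
    if (length(bad))
        stop("unknown deliverer source(s): ", paste(bad, collapse = ", "))
    set.seed(seed)
    lowPool <- which(bulk$baselineMean < recipientMax)
    groups <- split(bulk$sources$source, bulk$sources$group)
    nShared <- round(withinGroupCor * cargoSize)
    needed <- sum(vapply(groups, function(src)
        nShared + length(src) * (cargoSize - nShared), 0))
    if (length(lowPool) < needed)
        stop("not enough recipient-silent genes (", length(lowPool),
             ") for the requested cargo sets (", needed, ")")
    cargo <- list()
    for (g in names(groups)) {
        shared <- sample(lowPool, nShared)
        for (s in groups[[g]])
            cargo[[s]] <- sort(c(shared,
                sample(setdiff(lowPool, shared), cargoSize - nShared)))
    }
    cargo <- cargo[bulk$sources$source]
    flags <- stats::setNames(bulk$sources$source %in% deliverers,
                             bulk$sources$source)
    design <- list(bulk = bulk, cargoSets = cargo, deliverers = flags,
                   slope = slope, baseLevel = baseLevel,
                   nonDelivererLevel = nonDelivererLevel,
                   cargoAbundance = cargoAbundance,
                   recipientMax = recipientMax, seed = seed)
    class(design) <- "DeliveryDesign"
    design
}

#' Generate synthetic EV transcriptomes
#'
#' One column per EV source and replicate: a diluted copy of the
#' producer-cell background plus the source's cargo genes at high
#' abundance (above the downstream 100-normalized-count threshold).
#' Same-group sources share cargo genes according to the design's
#' within-group correlation.
#'
#' @param design a \code{\link{deliveryDesign}}.
#' @param nEvReplicates columns per source (default 3).
#' @return an \linkS4class{EVExperiment} with colData columns source and
#'   sourceGroup.
#' @export
generateEVTranscriptomes <- function(design, nEvReplicates = 3) {
    stopifnot(inherits(design, "DeliveryDesign"))
    bulk <- design$bulk
    expressed <- bulk$baselineMean >= 1
    over <- vapply(design$cargoSets, function(s) sum(expressed[s]), 0L)
    if (any(over > 0))
        stop("cargo set of ", names(over)[which(over > 0)[1]],
             " overlaps recipient-expressed baseline")
    set.seed(design$seed + 1L)
    srcs <- bulk$sources$source
    cols <- as.vector(vapply(srcs, function(s)
        sprintf("%s_EV_r%d", s, seq_len(nEvReplicates)),
        character(nEvReplicates)))
    counts <- matrix(0, bulk$nGenes, length(cols),
                     dimnames = list(bulk$genes, cols))
    libFactor <- exp(stats::rnorm(length(cols), 0, bulk$librarySizeSigma))
    j <- 0
    for (s in srcs) {
        mu0 <- 0.2 * bulk$baselineMean
        mu0[design$cargoSets[[s]]] <- design$cargoAbundance
        for (r in seq_len(nEvReplicates)) {
            j <- j + 1
            counts[, j] <- stats::rnbinom(bulk$nGenes,
                                          mu = mu0 * libFactor[j],
                                          size = 1 / bulk$dispersion)
        }
    }
    md <- data.frame(
        source = rep(srcs, each = nEvReplicates),
        sourceGroup = rep(bulk$sources$group, each = nEvReplicates),
        stringsAsFactors = FALSE)
    EVExperiment(counts, md)
}
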