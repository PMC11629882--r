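#' Define per-source EV gene sets
#'
#' Two modes. \code{"abundance"}: genes whose mean normalized count
#' within a source's EV samples is strictly above \code{threshold}
#' (default 100). \code{"enrichment"}: genes significantly up-regulated
#' (\code{\link{nbWaldDE}}, adjusted p below \code{alpha}) in a source's
#' EVs versus at least \code{minOthers} other EV sources.
#'
#' @param evExperiment \linkS4class{EVExperiment} of EV transcriptomes
#'   with a \code{source} colData column.
#' @param mode "abundance" or "enrichment".
#' @param threshold abundance cutoff in normalized counts (default 100).
#' @param alpha DE significance threshold for enrichment mode.
#' @param minOthers minimum number of other sources a gene must be
#'   enriched against (default 3).
#' @return named list of gene sets, one per source.
#' @export
defineEVGeneSets <- function(evExperiment, mode = c("abundance", "enrichment"),
                             threshold = 100, alpha = 0.05, minOthers = 3) {
    stopifnot(is(evExperiment, "EVExperiment"))
    mode <- match.arg(mode)
    md <- as.data.frame(colData(evExperiment))
    if (!"source" %in% names(md))
        stop("EV experiment needs a 'source' colData column")
    sources <- unique(md$source)
    x <- normalizedCounts(evExperiment)
    if (mode == "abundance") {
        sets <- lapply(sources, function(s) {
            m <- rowMeans(x[, md$source == s, drop = FALSE])
            rownames(x)[m > threshold]
        })
        names(sets) <- sources
        return(sets)
    }
    if (length(sources) < minOthers + 1)
        stop("enrichment mode needs at least ", minOthers + 1, " sources")
    reps <- table(md$source)
    if (any(reps < 2))
        stop("enrichment mode needs >= 2 replicates per source")
    sets <- vector("list", length(sources)); names(sets) <- sources
    for (s in sources) {
        nUp <- integer(nrow(x)); names(nUp) <- rownames(x)
        for (o in setdiff(sources, s)) {
            res <- nbWaldDE(evExperiment,
                            colnames(evExperiment)[md$source == s],
                            colnames(evExperiment)[md$source == o],
                            alpha = alpha)
            up <- significantGenes(res, "up")
            nUp[up] <- nUp[up] + 1L
        }
        sets[[s]] <- names(nUp)[nUp >= minOthers]
    }
    sets
}

#' Remove genes the recipient cells already express
#'
#' Drops from a tracking gene set every gene whose mean normalized count
#' in the control samples is strictly above \code{cutoff} (default 1).
#'
#' @param genes character vector (the candidate tracking set).
#' @param controlNorm normalized count matrix of control samples (or an
#'   \linkS4class{EVExperiment} restricted to controls).
#' @param cutoff mean normalized count above which a gene is considered
#'   recipient-expressed (default 1).
#' @return the filtered gene set; empty results carry a warning.
#' @export
filterRecipientExpressed <- function(genes, controlNorm, cutoff = 1) {
    x <- if (is(controlNorm, "EVExperiment")) normalizedCounts(controlNorm)
         else as.matrix(controlNorm)
    genes <- intersect(genes, rownames(x))
    m <- rowMeans(x[genes, , drop = FALSE])
    out <- genes[m <= cutoff]
    if (!length(out))
        warning("no tracking gene survives the recipient-expression filter; ",
                "profile is untrackable")
    out
}

#' Per-dose fold change of EV-derived transcripts in recipients
#'
#' For every tracking gene and dose, the fold of the treated over the
#' control mean normalized count, with zero means replaced by the
#' pseudocount (default 0.01) so folds stay finite and positive. The
#' per-dose summary is the mean of the per-gene log2 folds (the fold of
#' mean expression is also returned).
#'
#' @param treatedNorm normalized counts of the treated samples.
#' @param controlNorm normalized counts of the control samples.
#' @param doses numeric dose per treated sample (column).
#' @param genes tracking gene set (non-empty).
#' @param pseudocount replacement for zero means (default 0.01).
#' @return list with \code{perGene} (gene x dose fold matrix),
#'   \code{summary} (per-dose mean log2 fold) and \code{summaryOfMeans}
#'   (per-dose log2 fold of mean expression).
#' @export
uptakeFoldChange <- function(treatedNorm, controlNorm, doses, genes,
                             pseudocount = 0.01) {
    if (!length(genes)) stop("tracking gene set is empty")
    treatedNorm <- as.matrix(treatedNorm)
    controlNorm <- as.matrix(controlNorm)
    if (length(doses) != ncol(treatedNorm))
        stop("need one dose per treated sample")
    genes <- intersect(genes, rownames(treatedNorm))
    ctrl <- rowMeans(controlNorm[genes, , drop = FALSE])
    ctrl <- pmax(ctrl, pseudocount)
    lv <- sort(unique(doses))
    perGene <- sapply(lv, function(d) {
        tr <- rowMeans(treatedNorm[genes, doses == d, drop = FALSE])
        pmax(tr, pseudocount) / ctrl
    })
    perGene <- matrix(perGene, nrow = length(genes),
                      dimnames = list(genes, as.character(lv)))
    list(perGene = perGene,
         summary = colMeans(log2(perGene)),
         summaryOfMeans = log2(colSums(perGene * ctrl) / sum(ctrl)))
}

#' Fitted delivery slope over log10 dose
#'
#' Ordinary least squares of the per-dose summaries against log10(dose).
#'
#' @param summaries numeric per-dose summaries (e.g. mean log2 folds).
#' @param doses matching doses (>= 3 levels).
#' @return list with \code{slope} (per decade of dose), \code{se} and
#'   \code{intercept}.
#' @export
deliverySlope <- function(summaries, doses) {
    if (length(doses) < 3) stop("slope needs at least 3 dose levels")
    if (length(summaries) != length(doses))
        stop("one summary per dose required")
    x <- log10(doses)
    xc <- x - mean(x)
    slope <- sum(xc * summaries) / sum(xc^2)
    intercept <- mean(summaries) - slope * mean(x)
    rss <- sum((summaries - intercept - slope * x)^2)
    se <- sqrt(rss / (length(x) - 2) / sum(xc^2))
    list(slope = slope, se = se, intercept = intercept)
}

#' Classify an EV source as a dose-dependent deliverer
#'
#' A source delivers when its fitted uptake slope is positive and
#' exceeds \code{zCut} standard errors. With mean-log2-fold summaries
#' the summary slope equals the mean of the per-gene slopes, so
#' \code{\link{uptakeProfiles}} supplies the standard error of that mean
#' (spread of per-gene slopes over the tracking set), which has honest
#' degrees of freedom; the default \code{zCut} of 3 guards the call
#' across the 12 sources tested per study.
#'
#' @param slope,se fitted slope and its standard error.
#' @param zCut slope/se threshold (default 3).
#' @param minSlope material effect floor in log2 fold per decade of
#'   dose (default 0.5): a deliverer must show a visible rise, not just
#'   statistical drift.
#' @return logical flag.
#' @export
classifyDeliverer <- function(slope, se, zCut = 3, minSlope = 0.5) {
    is.finite(slope) && slope > minSlope && is.finite(se) && se > 0 &&
        slope / se > zCut
}

#' Full uptake profile of every EV source
#'
#' Composes the uptake stage: per-source EV gene sets (abundance mode by
#' default), removal of recipient-expressed genes, per-dose fold
#' changes in the treated recipients, the fitted slope over log10 dose
#' and the deliverer call.
#'
#' @param bulk \linkS4class{EVExperiment} of recipient samples with
#'   colData columns source, dose, treatment ("EV" vs controls).
#' @param evExperiment \linkS4class{EVExperiment} of EV transcriptomes
#'   with a source column.
#' @param mode,threshold passed to \code{\link{defineEVGeneSets}}.
#' @param expressedCutoff passed to
#'   \code{\link{filterRecipientExpressed}}.
#' @param pseudocount passed to \code{\link{uptakeFoldChange}}.
#' @param zCut,minSlope passed to \code{\link{classifyDeliverer}}.
#' @return data.frame: source, nTracking, slope, se, deliverer; the
#'   per-source fold details are attached as attribute
#'   \code{"profiles"}.
#' @export
uptakeProfiles <- function(bulk, evExperiment, mode = "abundance",
                           threshold = 100, expressedCutoff = 1,
                           pseudocount = 0.01, zCut = 3, minSlope = 0.5) {
    stopifnot(is(bulk, "EVExperiment"))
    md <- as.data.frame(colData(bulk))
    if (!all(c("source", "dose", "treatment") %in% names(md)))
        stop("bulk experiment needs source, dose, treatment colData")
    x <- normalizedCounts(bulk)
    ctrlCols <- md$treatment != "EV"
    evSets <- defineEVGeneSets(evExperiment, mode = mode,
                               threshold = threshold)
    profs <- list()
    out <- data.frame(source = names(evSets), nTracking = 0L,
                      slope = NA_real_, se = NA_real_, deliverer = FALSE,
                      stringsAsFactors = FALSE)
    for (i in seq_along(evSets)) {
        s <- names(evSets)[i]
        tracking <- filterRecipientExpressed(evSets[[s]],
                                             x[, ctrlCols, drop = FALSE],
                                             cutoff = expressedCutoff)
        out$nTracking[i] <- length(tracking)
        if (!length(tracking)) next
        treatedCols <- which(md$treatment == "EV" & md$source == s)
        fc <- uptakeFoldChange(x[, treatedCols, drop = FALSE],
                               x[, ctrlCols, drop = FALSE],
                               md$dose[treatedCols], tracking,
                               pseudocount = pseudocount)
        sl <- deliverySlope(fc$summary,
                            as.numeric(names(fc$summary)))
        # SE of the summary slope from the per-gene slope spread: the
        # summary slope is the mean of per-gene OLS slopes, whose
        # between-gene sd gives a standard error with honest df
        lx <- log10(as.numeric(colnames(fc$perGene)))
        xc <- lx - mean(lx)
        gSlopes <- as.numeric(log2(fc$perGene) %*% xc / sum(xc^2))
        seGenes <- stats::sd(gSlopes) / sqrt(length(gSlopes))
        out$slope[i] <- sl$slope
        out$se[i] <- if (is.finite(seGenes) && seGenes > 0) seGenes else sl$se
        out$deliverer[i] <- classifyDeliverer(out$slope[i], out$se[i],
                                              zCut, minSlope)
        profs[[s]] <- fc
    }
    attr(out, "profiles") <- profs
    out
}
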