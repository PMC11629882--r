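#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios rule: for
#' each sample, the factor is the median over reference genes of that
#' sample's count divided by the gene's geometric mean across samples.
#' Reference genes are those with a strictly positive count in every
#' sample; when no such gene exists the reference set falls back to
#' genes positive in at least \code{fallbackFraction} of samples (their
#' geometric means are taken over the positive entries only), which
#' keeps the estimator usable on sparse pseudobulk matrices.
#'
#' @param object an \linkS4class{EVExperiment} or raw count matrix.
#' @param fallbackFraction fraction of samples in which a gene must be
#'   positive to enter the fallback reference set (default 0.9).
#' @return positive numeric vector, one factor per sample, named.
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 100), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' computeSizeFactors(m)
#' @export
computeSizeFactors <- function(object, fallbackFraction = 0.9) {
    m <- if (is(object, "EVExperiment")) counts(object) else as.matrix(object)
    if (ncol(m) < 2) stop("size factors need at least 2 samples")
    allpos <- rowSums(m > 0) == ncol(m)
    if (any(allpos)) {
        ref <- m[allpos, , drop = FALSE]
        geo <- exp(rowMeans(log(ref)))
        sf <- apply(ref / geo, 2, stats::median)
    } else {
        frac <- rowMeans(m > 0)
        use <- frac >= fallbackFraction
        if (!any(use))
            stop("no gene is positive in all samples and none is positive ",
                 "in >= ", fallbackFraction * 100, "% of samples; ",
                 "cannot form a median-of-ratios reference set")
        ref <- m[use, , drop = FALSE]
        lg <- log(ref)
        lg[!is.finite(lg)] <- NA
        geo <- exp(rowMeans(lg, na.rm = TRUE))
        rat <- ref / geo
        rat[ref == 0] <- NA
        sf <- apply(rat, 2, stats::median, na.rm = TRUE)
    }
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor for sample(s): ",
             paste(colnames(m)[!is.finite(sf) | sf <= 0], collapse = ", "))
    stats::setNames(sf, colnames(m))
}

#' @describeIn EVExperiment size factors stored by
#'   \code{\link{normalizeCounts}} (NULL before normalization).
#' @export
setMethod("sizeFactors", "EVExperiment", function(object) {
    if (!"sizeFactor" %in% names(colData(object))) return(NULL)
    stats::setNames(colData(object)$sizeFactor, colnames(object))
})

#' Attach size factors and a normalized assay
#'
#' Computes median-of-ratios size factors (unless supplied) and stores
#' the per-sample factors in \code{colData} plus a \code{"normcounts"}
#' assay with counts divided by their sample's factor.
#'
#' @param object an \linkS4class{EVExperiment}.
#' @param sizeFactors optional precomputed positive factors.
#' @return the EVExperiment with \code{normcounts} assay attached.
#' @export
normalizeCounts <- function(object, sizeFactors = NULL) {
    stopifnot(is(object, "EVExperiment"))
    sf <- if (is.null(sizeFactors)) computeSizeFactors(object) else sizeFactors
    if (length(sf) != ncol(object) || any(sf <= 0))
        stop("need one positive size factor per sample")
    colData(object)$sizeFactor <- unname(sf)
    assay(object, "normcounts") <- sweep(counts(object), 2, sf, "/")
    object
}

#' @describeIn normalizeCounts the normalized count matrix; normalizes
#'   on the fly if no \code{normcounts} assay is present.
#' @export
normalizedCounts <- function(object) {
    stopifnot(is(object, "EVExperiment"))
    if (!"normcounts" %in% assayNames(object))
        object <- normalizeCounts(object)
    assay(object, "normcounts")
}
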