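#' @importFrom IRanges isDisjoint
NULL

#' @rdname PeakClusters-class
#' @param x a PeakClusters or OTFRSet object.
#' @export
setGeneric("peakCount", function(x) standardGeneric("peakCount"))

#' @rdname OTFRSet-class
#' @export
setGeneric("otfrRanges", function(x) standardGeneric("otfrRanges"))

#' @rdname OTFRSet-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("eValue", function(x) standardGeneric("eValue"))

# ---- PeakClusters accessors ----

#' @describeIn PeakClusters-class the peaks, in input order.
#' @export
clusterPeakRanges <- function(x) x@peaks

#' @describeIn PeakClusters-class GRanges of cluster extents with clusterId
#'   and peakCount metadata.
#' @export
clusterExtents <- function(x) x@extents

#' @describeIn PeakClusters-class integer clusterId per peak.
#' @export
clusterMembership <- function(x) x@membership

#' @describeIn PeakClusters-class member peaks of one cluster.
#' @param clusterId integer id of the wanted cluster.
#' @export
clusterMembers <- function(x, clusterId) {
    stopifnot(is(x, "PeakClusters"), length(clusterId) == 1L)
    x@peaks[x@membership == as.integer(clusterId)]
}

#' @rdname PeakClusters-class
#' @export
setMethod("peakCount", "PeakClusters",
          function(x) mcols(x@extents)$peakCount)

setMethod("show", "PeakClusters", function(object) {
    cat("PeakClusters with", length(object@extents), "clusters from",
        length(object@peaks), "peaks\n")
    if (length(object@extents)) {
        cnt <- mcols(object@extents)$peakCount
        cat("  peaks per cluster: min", min(cnt), "/ median",
            stats::median(cnt), "/ max", max(cnt), "\n")
    }
})

# ---- OTFRSet accessors ----

#' @rdname OTFRSet-class
#' @export
setMethod("otfrRanges", "OTFRSet", function(x) x@regions)

#' @rdname OTFRSet-class
#' @export
setMethod("peakCount", "OTFRSet", function(x) mcols(x@regions)$peakCount)

#' @describeIn OTFRSet-class total length L of the regions, in bp.
#' @export
setMethod("totalLength", "OTFRSet", function(x) sum(as.numeric(width(x@regions))))

#' @describeIn OTFRSet-class the peak-count threshold i.
#' @export
iMin <- function(x) x@iMin

setMethod("length", "OTFRSet", function(x) length(x@regions))

setMethod("show", "OTFRSet", function(object) {
    cat("OTFRSet:", length(object@regions), "regions at i >=", object@iMin,
        if (object@trimmed) sprintf("(Gaussian-trimmed, %.3g sigma)",
                                    object@kSigma) else "(untrimmed)", "\n")
    cat("  total length:", totalLength(object), "bp\n")
})

# ---- EnrichmentResult accessors ----

#' @rdname EnrichmentResult-class
#' @export
setMethod("eValue", "EnrichmentResult", function(x) x@eValue)

#' @describeIn EnrichmentResult-class observed in-OTFR fraction P*.
#' @export
pStar <- function(x) x@pStar

#' @describeIn EnrichmentResult-class expected fraction P = L/G.
#' @export
pExpected <- function(x) x@pExp

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult (i >= %s): E = %.4g\n",
                ifelse(is.na(object@iMin), "?", object@iMin), object@eValue))
    cat(sprintf("  P* = %d/%d = %.4g; P = %g/%g = %.4g\n",
                object@nIn, object@nTotal, object@pStar,
                object@otfrLength, object@genomeLength, object@pExp))
})

# ---- BootstrapSummary ----

#' @describeIn BootstrapSummary-class the B resampled E values.
#' @param x a BootstrapSummary.
#' @export
bootValues <- function(x) x@values

#' @describeIn BootstrapSummary-class the confidence interval as c(low, high).
#' @export
bootCI <- function(x) c(low = x@ciLow, high = x@ciHigh)

setMethod("show", "BootstrapSummary", function(object) {
    cat(sprintf("BootstrapSummary: B = %d, mean E = %.4g, sd = %.3g\n",
                object@nIterations, object@mean, object@sd))
    cat(sprintf("  %.0f%% CI [%.4g, %.4g]; normality chi2 p = %.3g\n",
                100 * object@ciLevel, object@ciLow, object@ciHigh,
                object@chi2P))
})

# ---- Motif classes ----

#' @describeIn MotifMatrix-class motif width (number of columns).
#' @param x a MotifMatrix or LogOddsMatrix.
#' @export
motifWidth <- function(x) {
    if (is(x, "MotifMatrix")) ncol(x@counts) else ncol(x@values)
}

#' @describeIn MotifMatrix-class the motif identifier.
#' @export
motifId <- function(x) x@motifId

#' @describeIn MotifMatrix-class the count matrix.
#' @export
motifCounts <- function(x) x@counts

setMethod("show", "MotifMatrix", function(object) {
    cat(sprintf("MotifMatrix %s (%s), width %d, consensus %s\n",
                object@motifId, object@name, ncol(object@counts),
                motifConsensus(object)))
})

setMethod("show", "LogOddsMatrix", function(object) {
    cat(sprintf("LogOddsMatrix %s (%s), width %d, score range [%.3g, %.3g]\n",
                object@motifId, object@name, ncol(object@values),
                object@minScore, object@maxScore))
})

setMethod("show", "AlleleWindowPair", function(object) {
    cat(sprintf("AlleleWindowPair %s: %s -> %s at offset %d (len %d)\n",
                object@snpId,
                substr(object@seqRef, object@snpOffset + 1L,
                       object@snpOffset + 1L),
                substr(object@seqAlt, object@snpOffset + 1L,
                       object@snpOffset + 1L),
                object@snpOffset, nchar(object@seqRef)))
})
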