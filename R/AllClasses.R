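#' @import methods
#' @importFrom BiocGenerics sort unique setdiff
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps
#'   reduce coverage seqnames start end width strand strand<- mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors DataFrame queryHits subjectHits Rle runValue
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- sortSeqlevels
#'   seqlevelsInUse keepSeqlevels Seqinfo seqinfo
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom stats rnorm runif qnorm pchisq sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' PeakClusters: transitively overlapping ChIP-seq peaks
#'
#' Groups a set of ChIP-seq peaks into maximal clusters under single-linkage
#' overlap (two peaks belong to the same cluster when they share at least one
#' base, directly or through intermediates; abutting peaks do not overlap).
#' Cluster extents are numbered 1..n in (chromosome, start) order.
#'
#' @slot peaks GRanges of the input peaks, in input order, with at least a
#'   \code{factor} metadata column when factors are known.
#' @slot extents GRanges of cluster spans with metadata columns
#'   \code{clusterId} and \code{peakCount}.
#' @slot membership integer vector, parallel to \code{peaks}, giving the
#'   clusterId each peak belongs to.
#' @export
setClass("PeakClusters",
    representation(peaks = "GRanges", extents = "GRanges",
                   membership = "integer"))

setValidity("PeakClusters", function(object) {
    msg <- NULL
    if (length(object@membership) != length(object@peaks))
        msg <- c(msg, "membership must be parallel to peaks")
    md <- mcols(object@extents)
    if (length(object@extents) &&
        !all(c("clusterId", "peakCount") %in% colnames(md)))
        msg <- c(msg, "extents need clusterId and peakCount columns")
    if (length(object@extents)) {
        cnt <- tabulate(object@membership, nbins = length(object@extents))
        if (!identical(as.integer(md$peakCount), cnt))
            msg <- c(msg, "peakCount must equal the number of member peaks")
        if (any(md$peakCount < 1L))
            msg <- c(msg, "every cluster must have at least one member")
    }
    if (is.null(msg)) TRUE else msg
})

#' OTFRSet: overlapping TF-binding regions at a peak-count threshold
#'
#' The regions retained from a \linkS4class{PeakClusters} object: clusters
#' whose total peak count is at least \code{iMin}, each reduced to its
#' (optionally Gaussian-trimmed) interval.
#'
#' @slot regions GRanges with metadata columns \code{clusterId} and
#'   \code{peakCount}; regions are pairwise disjoint.
#' @slot iMin integer threshold i: minimum peaks per cluster.
#' @slot trimmed logical, whether Gaussian density trimming was applied.
#' @slot kSigma numeric, half-width of the retained density area in standard
#'   deviations (2 keeps approximately the central 95\%).
#' @export
setClass("OTFRSet",
    representation(regions = "GRanges", iMin = "integer",
                   trimmed = "logical", kSigma = "numeric"))

setValidity("OTFRSet", function(object) {
    msg <- NULL
    md <- mcols(object@regions)
    if (length(object@regions) &&
        !all(c("clusterId", "peakCount") %in% colnames(md)))
        msg <- c(msg, "regions need clusterId and peakCount columns")
    if (!is.na(object@iMin) && object@iMin < 2L)
        msg <- c(msg, "iMin must be >= 2")
    if (length(object@regions) > 1L &&
        !isDisjoint(object@regions))
        msg <- c(msg, "OTFR regions must be pairwise disjoint")
    if (length(object@kSigma) != 1L || object@kSigma <= 0)
        msg <- c(msg, "kSigma must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' EnrichmentResult: the enrichment statistic E(i)
#'
#' E = P*/P where P* = nIn/nTotal is the observed fraction of SNPs inside
#' OTFRs and P = L/G is the fraction expected under a uniform genomic
#' distribution (L = total OTFR length, G = genome length).
#'
#' @slot iMin integer threshold the OTFRs were built at (NA when unknown).
#' @slot nIn,nTotal integer SNP counts.
#' @slot otfrLength,genomeLength numeric lengths in bp.
#' @slot pStar,pExp,eValue numeric; eValue = pStar/pExp.
#' @export
setClass("EnrichmentResult",
    representation(iMin = "integer", nIn = "integer", nTotal = "integer",
                   otfrLength = "numeric", genomeLength = "numeric",
                   pStar = "numeric", pExp = "numeric", eValue = "numeric"))

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (object@nIn < 0L || object@nIn > object@nTotal)
        msg <- c(msg, "need 0 <= nIn <= nTotal")
    if (object@otfrLength <= 0 || object@otfrLength > object@genomeLength)
        msg <- c(msg, "need 0 < otfrLength <= genomeLength")
    if (!isTRUE(all.equal(object@eValue, object@pStar / object@pExp)))
        msg <- c(msg, "eValue must equal pStar/pExp")
    if (is.null(msg)) TRUE else msg
})

#' BootstrapSummary: resampling uncertainty of E(i)
#'
#' Produced by \code{\link{bootstrapEnrichment}}: B resampled values of E,
#' their mean, population standard deviation, a normal-approximation
#' confidence interval, and a Pearson chi-squared check of normality of the
#' bootstrap distribution.
#'
#' @slot nIterations integer B.
#' @slot seed integer seed the resampling was run under.
#' @slot values numeric vector of the B bootstrap E values.
#' @slot mean,sd,ciLevel,ciLow,ciHigh numeric summary of the values.
#' @slot chi2Stat,chi2P numeric and @slot chi2Df integer: Pearson
#'   chi-squared goodness-of-fit against the fitted normal (NA when B < 50
#'   or the values are degenerate).
#' @export
setClass("BootstrapSummary",
    representation(nIterations = "integer", seed = "integer",
                   values = "numeric", mean = "numeric", sd = "numeric",
                   ciLevel = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   chi2Stat = "numeric", chi2Df = "integer",
                   chi2P = "numeric"))

setValidity("BootstrapSummary", function(object) {
    msg <- NULL
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (!(object@ciLow <= object@mean && object@mean <= object@ciHigh))
        msg <- c(msg, "need ciLow <= mean <= ciHigh")
    if (is.null(msg)) TRUE else msg
})

#' MotifMatrix: a position frequency matrix
#'
#' Raw base counts per motif column, as distributed by JASPAR.
#'
#' @slot motifId character identifier (e.g. "MA0004.1").
#' @slot name character TF name.
#' @slot counts 4 x w non-negative matrix with rownames A, C, G, T; every
#'   column has a positive sum.
#' @export
setClass("MotifMatrix",
    representation(motifId = "character", name = "character",
                   counts = "matrix"))

setValidity("MotifMatrix", function(object) {
    msg <- NULL
    cn <- object@counts
    if (!is.numeric(cn) || nrow(cn) != 4L)
        msg <- c(msg, "counts must be a numeric 4 x w matrix")
    else {
        if (!identical(rownames(cn), c("A", "C", "G", "T")))
            msg <- c(msg, "counts rows must be named A, C, G, T")
        if (ncol(cn) < 1L) msg <- c(msg, "motif width must be >= 1")
        if (any(cn < 0)) msg <- c(msg, "counts must be non-negative")
        if (ncol(cn) >= 1L && any(colSums(cn) <= 0))
            msg <- c(msg, "every column must have a positive sum")
    }
    if (is.null(msg)) TRUE else msg
})

#' LogOddsMatrix: a PFM converted to log-odds scoring form
#'
#' @slot motifId,name character, copied from the source PFM.
#' @slot values 4 x w numeric log2-odds matrix (rownames A, C, G, T).
#' @slot minScore,maxScore numeric sums of columnwise minima/maxima; the
#'   relative score of a window is (raw - minScore)/(maxScore - minScore).
#' @export
setClass("LogOddsMatrix",
    representation(motifId = "character", name = "character",
                   values = "matrix", minScore = "numeric",
                   maxScore = "numeric"))

setValidity("LogOddsMatrix", function(object) {
    if (object@minScore >= object@maxScore)
        "minScore must be < maxScore" else TRUE
})

#' AlleleWindowPair: the two allelic sequences around a SNP
#'
#' Equal-length reference and alternate sequence windows differing only at
#' the substituted base, plus the 0-based offset of that base.
#'
#' @slot snpId character.
#' @slot seqRef,seqAlt character over A/C/G/T, equal length.
#' @slot snpOffset integer, 0-based index of the variant base.
#' @export
setClass("AlleleWindowPair",
    representation(snpId = "character", seqRef = "character",
                   seqAlt = "character", snpOffset = "integer"))

setValidity("AlleleWindowPair", function(object) {
    msg <- NULL
    if (nchar(object@seqRef) != nchar(object@seqAlt))
        msg <- c(msg, "seqRef and seqAlt must have equal length (substitutions only)")
    if (object@snpOffset < 0L || object@snpOffset >= nchar(object@seqRef))
        msg <- c(msg, "snpOffset must index a base of seqRef")
    if (nchar(object@seqRef) == nchar(object@seqAlt)) {
        r <- strsplit(object@seqRef, "")[[1]]
        a <- strsplit(object@seqAlt, "")[[1]]
        diff <- which(r != a)
        if (length(diff) > 1L || (length(diff) == 1L &&
                                  diff != object@snpOffset + 1L))
            msg <- c(msg, "sequences may differ only at snpOffset")
    }
    if (is.null(msg)) TRUE else msg
})
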