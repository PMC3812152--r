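# Synthetic data with known ground truth: clustered peak tracks (hotspot
# model), SNP sets with a controlled in-OTFR placement probability, and
# motif disruption fixtures.

.withSeed <- function(seed, expr) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulate a clustered ChIP-seq peak track
#'
#' Peak centers follow a hotspot mixture: with probability
#' \code{hotspotFraction} a peak is displaced normally
#' (sd = \code{hotspotSd}) around one of \code{nHotspots} uniformly placed
#' hotspot centers, otherwise it is uniform over the genome. Lengths are
#' normal, clipped to >= 1 bp, and peaks are clipped to chromosome bounds.
#' Factor labels cycle round-robin over \code{nFactors} synthetic TF names.
#'
#' The defaults describe the package's standard validation fixture: a
#' 10 Mb genome split over two chromosomes carrying 5,000 peaks of roughly
#' ENCODE-like width (300 +/- 100 bp), 70\% of them concentrated in 200
#' hotspots.
#'
#' @param nPeaks number of peaks (default 5000).
#' @param genomeLength total genome length in bp (default 1e7), divided
#'   equally over \code{nChrom} chromosomes.
#' @param nChrom number of chromosomes (default 2).
#' @param nFactors number of distinct TF labels (default 10).
#' @param peakLenMean,peakLenSd peak length distribution in bp
#'   (default 300 +/- 100).
#' @param nHotspots number of hotspot centers (default 200).
#' @param hotspotSd normal displacement around a hotspot center, bp
#'   (default 500).
#' @param hotspotFraction probability a peak is hotspot-associated
#'   (default 0.7).
#' @param seed integer seed; identical seeds give identical tracks.
#' @return GRanges of peaks with \code{factor} and \code{score} metadata
#'   and seqlengths set.
#' @export
simulatePeaks <- function(nPeaks = 5000L, genomeLength = 1e7, nChrom = 2L,
                          nFactors = 10L, peakLenMean = 300,
                          peakLenSd = 100, nHotspots = 200L,
                          hotspotSd = 500, hotspotFraction = 0.7,
                          seed = 1L) {
    stopifnot(hotspotFraction >= 0, hotspotFraction <= 1, peakLenMean > 0,
              nPeaks >= 1L, nChrom >= 1L, genomeLength >= nChrom)
    chromLen <- rep(floor(genomeLength / nChrom), nChrom)
    chromNames <- paste0("chr", seq_len(nChrom))
    .withSeed(seed, {
        hotChrom <- sample.int(nChrom, nHotspots, replace = TRUE,
                               prob = chromLen)
        hotPos <- floor(runif(nHotspots) * chromLen[hotChrom]) + 1
        isHot <- runif(nPeaks) < hotspotFraction
        chrom <- integer(nPeaks)
        center <- numeric(nPeaks)
        nHot <- sum(isHot)
        if (nHot > 0L && nHotspots > 0L) {
            pick <- sample.int(nHotspots, nHot, replace = TRUE)
            chrom[isHot] <- hotChrom[pick]
            center[isHot] <- round(rnorm(nHot, hotPos[pick], hotspotSd))
        }
        nUni <- sum(!isHot)
        if (nUni > 0L) {
            chrom[!isHot] <- sample.int(nChrom, nUni, replace = TRUE,
                                        prob = chromLen)
            center[!isHot] <- floor(runif(nUni) * chromLen[chrom[!isHot]]) + 1
        }
        len <- pmax(1, round(rnorm(nPeaks, peakLenMean, peakLenSd)))
        s <- pmax(1, round(center - len / 2))
        e <- pmin(chromLen[chrom], s + len - 1)
        s <- pmin(s, e)  # keeps width >= 1 at the right edge
        GRanges(factor(chromNames[chrom], levels = chromNames),
                IRanges(s, e),
                factor = rep_len(sprintf("TF%02d", seq_len(nFactors)),
                                 nPeaks),
                score = round(runif(nPeaks, 100, 1000)),
                seqinfo = Seqinfo(chromNames, chromLen))
    })
}

#' Simulate SNPs with known in-OTFR placement probability
#'
#' With probability \code{q} a SNP position is uniform over the OTFR union,
#' otherwise uniform over its complement within the chromosomes. Reference
#' and alternate alleles are a uniformly drawn pair of distinct bases. By
#' construction the expected enrichment is E = q * G / L (see
#' \code{\link{expectedEnrichment}}), so q = L/G is the uniform null.
#'
#' @param nSnps number of SNPs.
#' @param q in-OTFR placement probability, in [0, 1].
#' @param otfrs an \linkS4class{OTFRSet} or GRanges of regions.
#' @param seqlen named vector of chromosome lengths (defaults to the
#'   seqlengths carried by \code{otfrs}).
#' @param seed integer seed.
#' @return GRanges of width-1 SNPs with id, ref, alt, pValue, oddsRatio
#'   metadata (association fields NA).
#' @export
simulateSnps <- function(nSnps, q, otfrs, seqlen = NULL, seed = 1L) {
    stopifnot(q >= 0, q <= 1, nSnps >= 1L)
    regions <- if (is(otfrs, "OTFRSet")) otfrRanges(otfrs) else otfrs
    un <- reduce(granges(regions))
    if (is.null(seqlen)) seqlen <- seqlengths(un)
    if (anyNA(seqlen) || !length(seqlen))
        stop("chromosome lengths are required (seqlen or seqlengths(otfrs))")
    L <- sum(as.numeric(width(un)))
    G <- sum(as.numeric(seqlen))
    if (q > 0 && L == 0)
        stop("cannot place SNPs inside an empty OTFR union (q > 0)")
    if (q < 1 && L >= G)
        stop("OTFR union covers the genome; cannot place SNPs outside")
    chroms <- GRanges(names(seqlen), IRanges(1, seqlen))
    comp <- setdiff(chroms, un)
    .withSeed(seed, {
        inside <- runif(nSnps) < q
        pos <- rep(NA_real_, nSnps)
        chrom <- rep(NA_character_, nSnps)
        placeUniform <- function(segs, k) {
            wseg <- as.numeric(width(segs))
            j <- sample.int(length(segs), k, replace = TRUE, prob = wseg)
            list(chrom = as.character(seqnames(segs))[j],
                 pos = start(segs)[j] +
                     floor(runif(k) * wseg[j]))
        }
        if (any(inside)) {
            p <- placeUniform(un, sum(inside))
            chrom[inside] <- p$chrom; pos[inside] <- p$pos
        }
        if (any(!inside)) {
            p <- placeUniform(comp, sum(!inside))
            chrom[!inside] <- p$chrom; pos[!inside] <- p$pos
        }
        refIdx <- sample.int(4L, nSnps, replace = TRUE)
        altIdx <- 1L + (refIdx - 1L + sample.int(3L, nSnps,
                                                 replace = TRUE)) %% 4L
        gr <- GRanges(chrom, IRanges(pos, width = 1L))
        mcols(gr)$id <- sprintf("snp%06d", seq_len(nSnps))
        mcols(gr)$ref <- .BASES[refIdx]
        mcols(gr)$alt <- IRanges::CharacterList(as.list(.BASES[altIdx]))
        mcols(gr)$pValue <- rep(NA_real_, nSnps)
        mcols(gr)$oddsRatio <- rep(NA_real_, nSnps)
        seqlengths(gr) <- seqlen[seqlevels(gr)]
        gr
    })
}

#' Motif disruption fixture
#'
#' Embeds the motif consensus in random flanks and substitutes the base at
#' one column with that column's minimum-count base (among bases other than
#' the consensus base; ties resolved in A, C, G, T order). Disrupting a
#' maximum-information column drops the relative score by exactly that
#' column's contribution; disrupting a uniform column leaves it unchanged.
#'
#' @param motif a \linkS4class{MotifMatrix}.
#' @param disruptPosition 0-based column to disrupt (0 <= pos < width).
#' @param seed integer seed for the random flanks.
#' @param flank flank length in bp (default: motif width - 1, the minimal
#'   complete scan, floored at 1).
#' @return an \linkS4class{AlleleWindowPair}.
#' @export
simulateMotifCase <- function(motif, disruptPosition, seed = 1L,
                              flank = NULL) {
    stopifnot(is(motif, "MotifMatrix"))
    w <- motifWidth(motif)
    stopifnot(disruptPosition >= 0, disruptPosition < w)
    if (is.null(flank)) flank <- max(w - 1L, 1L)
    cons <- motifConsensus(motif)
    col <- motifCounts(motif)[, disruptPosition + 1L]
    consBase <- substr(cons, disruptPosition + 1L, disruptPosition + 1L)
    others <- setdiff(.BASES, consBase)
    altBase <- others[which.min(col[others])]
    .withSeed(seed, {
        flanks <- sample(.BASES, 2L * flank, replace = TRUE)
        seqRef <- paste0(paste(flanks[seq_len(flank)], collapse = ""),
                         cons,
                         paste(flanks[flank + seq_len(flank)],
                               collapse = ""))
        seqAlt <- seqRef
        off <- flank + disruptPosition
        substr(seqAlt, off + 1L, off + 1L) <- altBase
        alleleWindowPair(paste0(motif@motifId, "_pos", disruptPosition),
                         seqRef, seqAlt, off)
    })
}

#' Ground-truth enrichment of a simulated SNP set
#'
#' For SNPs placed inside the OTFR union with probability q, the expected
#' enrichment is E = q * G / L.
#'
#' @param q in-OTFR placement probability.
#' @param otfrLength total OTFR length L (0 < L <= G).
#' @param genomeLength genome length G.
#' @return the expected E value.
#' @examples
#' expectedEnrichment(0.4, 1e5, 1e6)  # 4
#' @export
expectedEnrichment <- function(q, otfrLength, genomeLength) {
    stopifnot(otfrLength > 0, otfrLength <= genomeLength, q >= 0, q <= 1)
    q * genomeLength / otfrLength
}
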