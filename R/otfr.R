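# OTFR construction: single-linkage clustering of overlapping peaks,
# coverage-weighted Gaussian density trimming, and SNP annotation.

#' Cluster transitively overlapping peaks
#'
#' Groups peaks into maximal connected components under pairwise overlap of
#' at least one base. Abutting peaks (end of one equal to start of the next
#' in half-open terms) do not overlap. Clusters are numbered 1..n by
#' (chromosome, start); singleton peaks form size-1 clusters.
#'
#' @param peaks GRanges of peaks (strand is ignored); may be unsorted and
#'   span several chromosomes.
#' @return a \linkS4class{PeakClusters} object.
#' @examples
#' p <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 6, 9), c(10, 15, 20)))
#' clusterPeaks(p)
#' @export
clusterPeaks <- function(peaks) {
    stopifnot(is(peaks, "GRanges"))
    if (!length(peaks))
        return(new("PeakClusters", peaks = peaks,
                   extents = GRanges(clusterId = integer(0),
                                     peakCount = integer(0)),
                   membership = integer(0)))
    ug <- granges(peaks)
    strand(ug) <- "*"
    ext <- reduce(ug, min.gapwidth = 0L)
    ext <- sort(sortSeqlevels(ext))
    hit <- findOverlaps(ug, ext, select = "first")
    mcols(ext)$clusterId <- seq_along(ext)
    mcols(ext)$peakCount <- tabulate(hit, nbins = length(ext))
    if (!is.null(mcols(peaks)$factor))
        mcols(ext)$factorSet <- unique(S4Vectors::splitAsList(
            mcols(peaks)$factor, factor(hit, levels = seq_along(ext))))
    new("PeakClusters", peaks = peaks, extents = ext,
        membership = as.integer(hit))
}

#' Per-base peak coverage of a cluster
#'
#' Sweep-line coverage of a set of member peaks, returned as maximal
#' constant-depth segments restricted to the covered bases (depth >= 1).
#'
#' @param members GRanges of the member peaks of one cluster (any GRanges
#'   works; segments cover exactly the union of the intervals).
#' @return GRanges of disjoint sorted segments with a \code{depth} metadata
#'   column. The conservation identity sum(depth * width) ==
#'   sum(width(members)) always holds.
#' @export
depthProfile <- function(members) {
    stopifnot(is(members, "GRanges"))
    if (!length(members)) return(GRanges(depth = integer(0)))
    ug <- granges(members)
    strand(ug) <- "*"
    seg <- as(coverage(ug), "GRanges")
    seg <- seg[seg$score > 0L]
    mcols(seg) <- DataFrame(depth = seg$score)
    sort(sortSeqlevels(seg))
}

#' Coverage-weighted positional moments of a cluster
#'
#' Mean and population standard deviation of genomic position weighted by
#' peak depth: each covered base contributes its center coordinate
#' (0-based convention, base b spans [b, b+1) and has center b + 0.5) with
#' weight equal to the number of peaks covering it. These are the moments of
#' the Gaussian approximation to the ChIP-seq peak density used by
#' \code{\link{gaussianTrim}}.
#'
#' @param members GRanges of the member peaks of one cluster (single
#'   chromosome).
#' @return named numeric c(mean, sd) in 0-based center coordinates.
#' @export
peakDensityMoments <- function(members) {
    seg <- depthProfile(members)
    .momentsFromSegments(start(seg), end(seg),
                         as.numeric(mcols(seg)$depth))
}

# closed-form weighted moments over 1-based closed segments [s, e] of
# constant depth d; base centers are s-0.5, s+0.5, ..., e-0.5
.momentsFromSegments <- function(s, e, d) {
    L <- e - s + 1
    c0 <- s - 0.5
    W <- sum(d * L)
    s1 <- sum(d * (L * c0 + L * (L - 1) / 2))
    s2 <- sum(d * (L * c0^2 + c0 * L * (L - 1) +
                   (L - 1) * L * (2 * L - 1) / 6))
    mu <- s1 / W
    v <- max(s2 / W - mu^2, 0)
    c(mean = mu, sd = sqrt(v))
}

#' Gaussian 2-sigma trimming of a cluster
#'
#' Approximates the peak density of a cluster by a Gaussian with the
#' coverage-weighted moments of \code{\link{peakDensityMoments}} and keeps
#' the central \code{kSigma}-sigma area (kSigma = 2 keeps about 95\% of the
#' density), intersected with the cluster extent. Degenerate clusters
#' (sd = 0) and empty intersections fall back to the untrimmed extent.
#'
#' @param members GRanges of the member peaks of one cluster.
#' @param kSigma positive half-width in standard deviations (default 2).
#' @return GRanges of length 1: the trimmed region.
#' @export
gaussianTrim <- function(members, kSigma = 2) {
    stopifnot(length(members) >= 1L, kSigma > 0)
    ext <- range(granges(members), ignore.strand = TRUE)
    stopifnot(length(ext) == 1L)
    m <- peakDensityMoments(members)
    .applyTrim(ext, m["mean"], m["sd"], kSigma)
}

.applyTrim <- function(ext, mu, sigma, kSigma) {
    if (sigma == 0) return(ext)
    s1 <- floor(mu - kSigma * sigma) + 1    # 0-based floor -> 1-based start
    e1 <- ceiling(mu + kSigma * sigma)      # 0-based exclusive == 1-based end
    s1 <- max(s1, start(ext))
    e1 <- min(e1, end(ext))
    if (s1 > e1) return(ext)
    out <- ext
    IRanges::ranges(out) <- IRanges(s1, e1)
    out
}

# trimmed (or raw) region of every cluster, in extent order
.clusterRegions <- function(clusters, trim = TRUE, kSigma = 2) {
    ext <- clusterExtents(clusters)
    if (!trim || !length(ext)) return(granges(ext))
    seg <- depthProfile(clusterPeakRanges(clusters))
    # a constant-depth segment can span two abutting clusters; clip each
    # overlapping (segment, extent) pair to the extent
    hit <- findOverlaps(seg, ext)
    g <- subjectHits(hit)
    s <- pmax(start(seg)[queryHits(hit)], start(ext)[g])
    e <- pmin(end(seg)[queryHits(hit)], end(ext)[g])
    d <- as.numeric(mcols(seg)$depth)[queryHits(hit)]
    L <- e - s + 1
    c0 <- s - 0.5
    W <- rowsum(d * L, g)[, 1L]
    S1 <- rowsum(d * (L * c0 + L * (L - 1) / 2), g)[, 1L]
    S2 <- rowsum(d * (L * c0^2 + c0 * L * (L - 1) +
                      (L - 1) * L * (2 * L - 1) / 6), g)[, 1L]
    mu <- S1 / W
    sigma <- sqrt(pmax(S2 / W - mu^2, 0))
    s1 <- pmax(floor(mu - kSigma * sigma) + 1, start(ext))
    e1 <- pmin(ceiling(mu + kSigma * sigma), end(ext))
    fb <- sigma == 0 | s1 > e1          # degenerate: keep the raw extent
    regions <- granges(ext)
    IRanges::ranges(regions) <- IRanges(ifelse(fb, start(ext), s1),
                                        ifelse(fb, end(ext), e1))
    regions
}

#' Build OTFRs at a peak-count threshold
#'
#' Retains clusters containing at least \code{iMin} peaks and reduces each
#' to its Gaussian-trimmed interval (see \code{\link{gaussianTrim}}).
#'
#' @param x GRanges of peaks or a precomputed \linkS4class{PeakClusters}.
#' @param iMin minimum number of overlapping TF binding loci, >= 2.
#' @param trim apply Gaussian density trimming (default TRUE; ignored in
#'   pointwise mode, whose regions are already density-thresholded).
#' @param kSigma trim half-width in standard deviations (default 2).
#' @param countMode how "i overlapping loci" is counted. The default
#'   "cluster" counts total member peaks of a transitively-overlapping
#'   cluster; "pointwise" is the stricter alternative keeping only the
#'   bases covered by at least \code{iMin} peaks simultaneously.
#' @return an \linkS4class{OTFRSet}.
#' @examples
#' p <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 6, 9), c(10, 15, 20)))
#' buildOtfr(p, iMin = 3)
#' @export
buildOtfr <- function(x, iMin = 2L, trim = TRUE, kSigma = 2,
                      countMode = c("cluster", "pointwise")) {
    if (iMin < 2) stop("iMin must be >= 2 (an OTFR needs overlapping peaks)")
    countMode <- match.arg(countMode)
    clusters <- if (is(x, "PeakClusters")) x else clusterPeaks(x)
    ext <- clusterExtents(clusters)
    if (countMode == "pointwise") {
        seg <- depthProfile(clusterPeakRanges(clusters))
        # abutting constant-depth segments are one contiguous run here
        out <- reduce(granges(seg[mcols(seg)$depth >= iMin]))
        hit <- findOverlaps(out, ext, select = "first")
        mcols(out) <- DataFrame(clusterId = mcols(ext)$clusterId[hit],
                                peakCount = mcols(ext)$peakCount[hit])
        return(new("OTFRSet", regions = out, iMin = as.integer(iMin),
                   trimmed = FALSE, kSigma = as.numeric(kSigma)))
    }
    regions <- .clusterRegions(clusters, trim = trim, kSigma = kSigma)
    keep <- mcols(ext)$peakCount >= iMin
    out <- regions[keep]
    mcols(out) <- DataFrame(clusterId = mcols(ext)$clusterId[keep],
                            peakCount = mcols(ext)$peakCount[keep])
    new("OTFRSet", regions = out, iMin = as.integer(iMin),
        trimmed = isTRUE(trim), kSigma = as.numeric(kSigma))
}

#' Annotate SNPs with peak depth and OTFR membership
#'
#' For each SNP reports the number of peaks covering its position (the
#' pointwise depth), whether it falls inside an OTFR (point containment;
#' OTFR regions are disjoint so the containing region is unique), and the
#' containing cluster's id and total peak count. This reproduces the
#' depth/cluster-count annotation pairs (e.g. "4/33") used to describe
#' candidate regulatory SNPs.
#'
#' @param snps GRanges of width-1 SNP positions with an \code{id} column
#'   (see \code{\link{readSnps}}).
#' @param peaks GRanges of the peaks the OTFRs were built from.
#' @param otfrs an \linkS4class{OTFRSet} (or GRanges with clusterId and
#'   peakCount metadata).
#' @return \linkS4class{DataFrame} with columns snp_id, chrom, pos0,
#'   depth_at_snp, cluster_id, cluster_peak_count, in_otfr.
#' @export
annotateSnps <- function(snps, peaks, otfrs) {
    stopifnot(is(snps, "GRanges"))
    regions <- if (is(otfrs, "OTFRSet")) otfrRanges(otfrs) else otfrs
    depth <- countOverlaps(granges(snps), granges(peaks),
                           ignore.strand = TRUE)
    hit <- findOverlaps(granges(snps), regions, select = "first",
                        ignore.strand = TRUE)
    id <- mcols(snps)$id
    if (is.null(id)) id <- paste0("snp", seq_along(snps))
    DataFrame(snp_id = id,
              chrom = as.character(seqnames(snps)),
              pos0 = start(snps) - 1L,
              depth_at_snp = as.integer(depth),
              cluster_id = mcols(regions)$clusterId[hit],
              cluster_peak_count = mcols(regions)$peakCount[hit],
              in_otfr = !is.na(hit))
}

#' Remove SNPs falling inside blacklisted regions
#'
#' Point-in-interval exclusion, used e.g. to drop the MHC region whose
#' dense genotyping inflates SNP counts.
#'
#' @param snps GRanges of SNP positions.
#' @param blacklist GRanges of regions to exclude (empty = identity).
#' @return the retained SNPs; the number removed is reported via
#'   \code{message()}.
#' @export
subtractBlacklist <- function(snps, blacklist) {
    stopifnot(is(snps, "GRanges"), is(blacklist, "GRanges"))
    if (!length(blacklist)) return(snps)
    drop <- overlapsAny(granges(snps), blacklist, ignore.strand = TRUE)
    message("subtractBlacklist: removed ", sum(drop), " of ",
            length(snps), " SNPs")
    snps[!drop]
}
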