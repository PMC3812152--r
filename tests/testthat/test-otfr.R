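test_that("overlap chains form one cluster; abutting peaks stay apart", {
    # BED [0,10), [5,15), [8,20) -> 1-based [1,10], [6,15], [9,20]
    chain <- gr1(c(1, 6, 9), c(10, 15, 20))
    pc <- clusterPeaks(chain)
    expect_length(clusterExtents(pc), 1L)
    expect_equal(start(clusterExtents(pc)), 1L)
    expect_equal(end(clusterExtents(pc)), 20L)
    expect_equal(peakCount(pc), 3L)

    abut <- gr1(c(1, 11), c(10, 20))  # BED [0,10) and [10,20)
    expect_length(clusterExtents(clusterPeaks(abut)), 2L)

    expect_length(clusterExtents(clusterPeaks(GRanges())), 0L)
})

test_that("clustering matches the overlap-graph oracle on random inputs", {
    set.seed(11)
    for (trial in 1:20) {
        peaks <- randomToyPeaks(50L, 1000L)
        pc <- clusterPeaks(peaks)
        expect_true(samePartition(clusterMembership(pc),
                                  bruteClusterLabels(peaks)))
        # ids follow (chrom, start) order of the extents
        ext <- clusterExtents(pc)
        expect_equal(mcols(ext)$clusterId, seq_along(ext))
        expect_false(is.unsorted(start(ext)))
    }
})

test_that("clustering is per chromosome with globally unique ids", {
    peaks <- suppressWarnings(c(gr1(c(1, 5), c(10, 20)),
                                gr1(3, 30, chrom = "chr2")))
    ext <- clusterExtents(clusterPeaks(peaks))
    expect_length(ext, 2L)
    expect_equal(as.character(seqnames(ext)), c("chr1", "chr2"))
    expect_equal(mcols(ext)$clusterId, 1:2)
})

test_that("depth profile segments match per-base counting", {
    seg <- depthProfile(gr1(c(1, 6, 9), c(10, 15, 20)))
    expect_equal(start(seg), c(1L, 6L, 9L, 11L, 16L))
    expect_equal(end(seg), c(5L, 8L, 10L, 15L, 20L))
    expect_equal(mcols(seg)$depth, c(1L, 2L, 3L, 2L, 1L))

    one <- depthProfile(gr1(4, 7))
    expect_equal(c(start(one), end(one), one$depth), c(4L, 7L, 1L))

    stack <- depthProfile(gr1(rep(1, 5), rep(100, 5)))
    expect_equal(mcols(stack)$depth, 5L)
    expect_equal(width(stack), 100L)

    set.seed(21)
    for (trial in 1:20) {
        peaks <- randomToyPeaks(40L, 800L)
        seg <- depthProfile(peaks)
        d <- bruteDepth(peaks, 900L)
        perBase <- rep(mcols(seg)$depth, width(seg))
        expect_equal(perBase, d[d > 0])
        # conservation: sum depth x length == total peak bp
        expect_equal(sum(as.numeric(mcols(seg)$depth) * width(seg)),
                     sum(as.numeric(width(peaks))))
    }
})

test_that("density moments match the discrete-uniform closed form", {
    stack <- gr1(rep(1, 5), rep(100, 5))       # BED [0,100) x 5
    m <- peakDensityMoments(stack)
    expect_equal(unname(m["mean"]), 50)
    expect_equal(unname(m["sd"]), sqrt((100^2 - 1) / 12), tolerance = 1e-12)
    # 2-sigma window [-7.7, 107.7] exceeds the extent -> unchanged
    tr <- gaussianTrim(stack)
    expect_equal(c(start(tr), end(tr)), c(1L, 100L))
})

test_that("degenerate and symmetric clusters trim sensibly", {
    single <- gr1(6, 6)                         # BED [5,6): sigma = 0
    expect_equal(unname(peakDensityMoments(single)["sd"]), 0)
    tr <- gaussianTrim(single)
    expect_equal(c(start(tr), end(tr)), c(6L, 6L))

    # symmetric triangular profile: trim symmetric about the midpoint
    tri <- gr1(c(1, 3, 5), c(10, 8, 6))        # depths 1,2,3,2,1 around 5
    m <- peakDensityMoments(tri)
    expect_equal(unname(m["mean"]), 5)
    tr <- gaussianTrim(tri, kSigma = 1)
    expect_equal((start(tr) - 1) + end(tr), 2 * 5)  # 0-based symmetry
})

test_that("trimming agrees with the per-base weighted-moment oracle", {
    set.seed(31)
    for (trial in 1:30) {
        peaks <- randomToyPeaks(sample(2:12, 1L), 400L)
        pc <- clusterPeaks(peaks)
        for (k in mcols(clusterExtents(pc))$clusterId) {
            members <- clusterMembers(pc, k)
            tr <- gaussianTrim(members)
            expect_equal(c(start(tr), end(tr)), bruteTrimInterval(members))
        }
        # the batch path used by buildOtfr matches the per-cluster path
        regions <- otfr:::.clusterRegions(pc)
        one <- vapply(mcols(clusterExtents(pc))$clusterId, function(k) {
            tr <- gaussianTrim(clusterMembers(pc, k))
            c(start(tr), end(tr))
        }, c(0, 0))
        expect_equal(rbind(start(regions), end(regions)), unname(one))
    }
})

test_that("buildOtfr filters by count, validates iMin, nests across i", {
    chain <- gr1(c(1, 6, 9), c(10, 15, 20))
    expect_length(buildOtfr(chain, iMin = 3), 1L)
    expect_length(buildOtfr(chain, iMin = 4), 0L)
    expect_error(buildOtfr(chain, iMin = 1), "iMin")

    singletons <- gr1(c(1, 100, 200), c(10, 110, 210))
    expect_length(buildOtfr(singletons, iMin = 2), 0L)

    peaks <- simulatePeaks(nPeaks = 400L, genomeLength = 2e5, seed = 5)
    pc <- clusterPeaks(peaks)
    prev <- NULL
    for (i in 2:12) {
        ot <- buildOtfr(pc, iMin = i)
        if (!is.null(prev)) {
            expect_lte(totalLength(ot), totalLength(prev))
            # every OTFR(i) region is an OTFR(i-1) region of the same cluster
            cur <- otfrRanges(ot)
            idx <- match(mcols(cur)$clusterId,
                         mcols(otfrRanges(prev))$clusterId)
            expect_false(anyNA(idx))
            expect_identical(granges(cur), granges(otfrRanges(prev)[idx]))
        }
        prev <- ot
    }
})

test_that("pointwise counting keeps only bases at depth >= i", {
    chain <- gr1(c(1, 6, 9), c(10, 15, 20))   # depths 1,2,3,2,1
    ot2 <- buildOtfr(chain, iMin = 2, countMode = "pointwise")
    expect_equal(c(start(otfrRanges(ot2)), end(otfrRanges(ot2))),
                 c(6L, 15L))
    ot3 <- buildOtfr(chain, iMin = 3, countMode = "pointwise")
    expect_equal(c(start(otfrRanges(ot3)), end(otfrRanges(ot3))),
                 c(9L, 10L))
    expect_equal(mcols(otfrRanges(ot3))$peakCount, 3L)

    set.seed(71)
    for (trial in 1:10) {
        peaks <- randomToyPeaks(40L, 600L)
        ot <- buildOtfr(peaks, iMin = 2, countMode = "pointwise")
        d <- bruteDepth(peaks, 700L)
        covered <- rep(FALSE, 700L)
        for (k in seq_along(otfrRanges(ot)))
            covered[start(otfrRanges(ot))[k]:end(otfrRanges(ot))[k]] <- TRUE
        expect_identical(covered, d >= 2L)
    }
})

test_that("SNP annotation reports pointwise depth and unique membership", {
    chain <- gr1(c(1, 6, 9), c(10, 15, 20))
    ot <- buildOtfr(chain, iMin = 3)
    # SNP at 0-based pos 9 (1-based 10): depth 3, inside the cluster
    ann <- annotateSnps(snpAt(10), chain, ot)
    expect_equal(ann$depth_at_snp, 3L)
    expect_equal(ann$cluster_peak_count, 3L)
    expect_true(ann$in_otfr)
    expect_equal(ann$pos0, 9L)

    # SNP at 0-based pos 10 with peak BED [0,10): not covered (half-open)
    ann <- annotateSnps(snpAt(11), gr1(1, 10), buildOtfr(chain, iMin = 3))
    expect_equal(ann$depth_at_snp, 0L)

    ann <- annotateSnps(snpAt(500), chain, ot)
    expect_equal(ann$depth_at_snp, 0L)
    expect_false(ann$in_otfr)
    expect_true(is.na(ann$cluster_id))
})

test_that("annotation depth matches brute force on random inputs", {
    set.seed(41)
    for (trial in 1:20) {
        peaks <- randomToyPeaks(60L, 1000L)
        ot <- buildOtfr(peaks, iMin = 2)
        pos <- sample.int(1000L, 50L)
        ann <- annotateSnps(snpAt(pos), peaks, ot)
        d <- bruteDepth(peaks, 1100L)
        expect_equal(ann$depth_at_snp, d[pos])
    }
})

test_that("blacklist subtraction equals the brute-force point filter", {
    snps <- snpAt(c(5, 15, 25), id = c("a", "b", "c"))
    expect_identical(subtractBlacklist(snps, GRanges()), snps)

    set.seed(51)
    for (trial in 1:10) {
        snps <- snpAt(sample.int(1000L, 100L),
                      id = sprintf("s%03d", 1:100))
        bl <- randomToyPeaks(5L, 1000L)
        kept <- suppressMessages(subtractBlacklist(snps, bl))
        inside <- vapply(start(snps), function(p)
            any(start(bl) <= p & p <= end(bl)), TRUE)
        expect_equal(mcols(kept)$id, mcols(snps)$id[!inside])
    }
})
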