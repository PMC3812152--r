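test_that("PFM to log-odds conversion matches hand arithmetic", {
    pfm <- motifMatrix("M1", cbind(c(4, 0, 0, 0),   # A column
                                   c(0, 4, 0, 0),   # C column
                                   c(1, 1, 1, 1)))  # uninformative column
    lom <- pfmToLogOdds(pfm, pseudocount = 0.8)
    # count 4 of 4, pseudocount 0.8 spread by uniform background:
    # log2((4 + 0.2)/(4.8)/0.25) = log2(3.5)
    expect_equal(unname(lom@values["A", 1L]), log2(3.5),
                 tolerance = 1e-12)
    expect_equal(unname(lom@values["T", 1L]), log2((0.2 / 4.8) / 0.25),
                 tolerance = 1e-12)
    expect_equal(unname(lom@values[, 3L]), rep(0, 4))
    # score range is the sum of columnwise extrema by definition
    expect_equal(lom@maxScore, sum(apply(lom@values, 2L, max)))
    expect_equal(lom@minScore, sum(apply(lom@values, 2L, min)))

    expect_error(pfmToLogOdds(pfm, pseudocount = 0), "pseudocount")
})

test_that("relative scores hit the exact extremes and hand values", {
    pfm <- motifMatrix("M1", cbind(c(4, 0, 0, 0), c(0, 4, 0, 0),
                                   c(0, 0, 4, 0)))
    lom <- pfmToLogOdds(pfm, pseudocount = 0.8)
    expect_identical(relativeScore(lom, "ACG"), 1)    # consensus
    expect_identical(relativeScore(lom, "TTT"), 0)    # anti-consensus
    # hand value for a one-mismatch window TCG
    hi <- log2((4.2 / 4.8) / 0.25)
    lo <- log2((0.2 / 4.8) / 0.25)
    expect_equal(relativeScore(lom, "TCG"),
                 (lo + 2 * hi - 3 * lo) / (3 * hi - 3 * lo),
                 tolerance = 1e-12)
    expect_message(s <- relativeScore(lom, "ANG"), "ambiguous")
    expect_true(is.na(s))
})

test_that("scores stay in [0,1] and respect reverse-complement symmetry", {
    set.seed(61)
    for (trial in 1:5) {
        counts <- matrix(rpois(4 * 6, 3) + ifelse(runif(24) < .2, 10, 0),
                         nrow = 4)
        counts[, colSums(counts) == 0] <- 1
        pfm <- motifMatrix("R", counts)
        lom <- pfmToLogOdds(pfm)
        # independently built reverse-complement matrix
        rcCounts <- counts[4:1, ncol(counts):1]
        rcLom <- pfmToLogOdds(motifMatrix("Rrc", rcCounts))
        wins <- vapply(1:20, function(i)
            paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""),
            "")
        sc <- relativeScore(lom, wins)
        expect_true(all(sc >= 0 & sc <= 1))
        rc <- vapply(wins, function(w)
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(w))), "")
        expect_equal(sc, relativeScore(rcLom, rc), tolerance = 1e-12)
    }
})

test_that("destroying the consensus base yields exactly one disrupted call", {
    # sharp 4-column motif (consensus ACGA): every column carries 25% of
    # the score range, so one consensus hit drops 1.0 -> 0.75 < 0.8
    m4 <- motifMatrix("M4", cbind(c(20, 0, 0, 0), c(0, 20, 0, 0),
                                  c(0, 0, 20, 0), c(20, 0, 0, 0)))
    lom <- pfmToLogOdds(m4)
    pair <- alleleWindowPair("v", "TTTTACGATTTT", "TTTTCCGATTTT", 4L)
    calls <- alleleImpact(pair, lom, threshold = 0.8, delta = 0.05)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$category, "disrupted")
    expect_equal(calls$strand, "+")
    expect_equal(calls$offset, 4L)
    expect_identical(calls$score_ref, 1)
    # score drop equals the disrupted column's contribution
    colDrop <- (max(lom@values[, 1L]) - min(lom@values[, 1L])) /
        (lom@maxScore - lom@minScore)
    expect_equal(calls$score_alt, 1 - colDrop, tolerance = 1e-12)
    expect_equal(calls$score_alt, 0.75, tolerance = 1e-12)
})

test_that("a no-op variant and a zero-information disruption are silent", {
    lom <- pfmToLogOdds(strongMotif())
    pair <- alleleWindowPair("dup", "ACGTACGT", "ACGTACGT", 3L)
    expect_equal(nrow(alleleImpact(pair, lom)), 0L)

    mixed <- motifMatrix("MIX", cbind(c(20, 0, 0, 0), c(0, 20, 0, 0),
                                      c(5, 5, 5, 5), c(0, 0, 20, 0),
                                      c(20, 0, 0, 0)))
    pairU <- simulateMotifCase(mixed, disruptPosition = 2L, seed = 72)
    callsU <- alleleImpact(pairU, pfmToLogOdds(mixed))
    expect_equal(nrow(callsU), 0L)
})

test_that("palindromic motifs score both strands equally", {
    pal <- motifMatrix("PAL", cbind(c(20, 0, 0, 0), c(0, 20, 0, 0),
                                    c(0, 0, 20, 0), c(0, 0, 0, 20)))
    # consensus ACGT is its own reverse complement
    lom <- pfmToLogOdds(pal)
    pair <- simulateMotifCase(pal, disruptPosition = 0L, seed = 73)
    calls <- alleleImpact(pair, lom)
    plus <- calls[calls$strand == "+", ]
    minus <- calls[calls$strand == "-", ]
    expect_equal(nrow(plus), nrow(minus))
    # mirrored offsets around the motif carry identical scores
    key <- function(x) x[order(x$offset), c("score_ref", "score_alt")]
    expect_equal(key(plus), key(minus), ignore_attr = TRUE)
})

test_that("raising the threshold never adds created or disrupted calls", {
    lom <- pfmToLogOdds(strongMotif())
    set.seed(74)
    for (trial in 1:10) {
        seqRef <- paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                        collapse = "")
        off <- sample(8:16, 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"),
                              substr(seqRef, off + 1, off + 1)), 1L)
        seqAlt <- seqRef
        substr(seqAlt, off + 1, off + 1) <- alt
        pair <- alleleWindowPair("t", seqRef, seqAlt, off)
        nCalls <- vapply(c(0.5, 0.7, 0.8, 0.9), function(thr) {
            calls <- alleleImpact(pair, lom, threshold = thr)
            sum(calls$category %in% c("created", "disrupted"))
        }, 0)
        expect_true(all(diff(nCalls) <= 0))
        # every emitted call satisfies exactly one category invariant
        calls <- alleleImpact(pair, lom, threshold = 0.5, delta = 0.05)
        if (nrow(calls)) {
            with(calls, for (r in seq_len(nrow(calls))) {
                sr <- score_ref[r]; sa <- score_alt[r]
                expect_equal(category[r] == "created",
                             sa >= 0.5 && sr < 0.5)
                expect_equal(category[r] == "disrupted",
                             sr >= 0.5 && sa < 0.5)
                expect_equal(category[r] %in% c("strengthened", "weakened"),
                             sr >= 0.5 && sa >= 0.5 && abs(sa - sr) > 0.05)
            })
        }
    }
})

test_that("allele windows are cut from the genome with checks", {
    genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
    snps <- snpAt(10, id = "v1")
    mcols(snps)$ref <- "C"   # genome base at 1-based pos 10 is C
    mcols(snps)$alt <- IRanges::CharacterList(list(c("A", "G")))
    pairs <- extractAlleleWindows(snps, genome, flank = 4L)
    expect_length(pairs, 2L)  # one per alt allele
    expect_equal(pairs[[1L]]@seqRef, "CGTACGTAC")
    expect_equal(pairs[[1L]]@snpOffset, 4L)
    expect_equal(substr(pairs[[1L]]@seqAlt, 5L, 5L), "A")
    expect_equal(substr(pairs[[2L]]@seqAlt, 5L, 5L), "G")

    # window clipped at the chromosome start keeps a correct offset
    snps2 <- snpAt(2, id = "v2")
    mcols(snps2)$ref <- "C"
    mcols(snps2)$alt <- IRanges::CharacterList(list("T"))
    p2 <- extractAlleleWindows(snps2, genome, flank = 4L)[[1L]]
    expect_equal(p2@snpOffset, 1L)
    expect_equal(p2@seqRef, "ACGTAC")

    mcols(snps)$ref <- "G"  # disagrees with the genome
    expect_warning(extractAlleleWindows(snps, genome, flank = 4L),
                   "differs from genome")
})
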