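# Brute-force per-base oracles used to cross-check the sweep-line /
# IRanges-based implementations on toy genomes, plus tiny fixture builders.

library(GenomicRanges)
library(IRanges)

gr1 <- function(s, e, chrom = "chr1", ...) GRanges(chrom, IRanges(s, e), ...)

snpAt <- function(pos1, chrom = "chr1", id = paste0("s", seq_along(pos1))) {
    GRanges(chrom, IRanges(pos1, width = 1L), id = id)
}

randomToyPeaks <- function(n, genomeLen, maxLen = 60L) {
    len <- sample.int(maxLen, n, replace = TRUE)
    s <- sample.int(genomeLen - maxLen, n, replace = TRUE)
    gr1(s, s + len - 1L, factor = sample(c("TFa", "TFb", "TFc"), n,
                                         replace = TRUE))
}

# per-base peak depth over bases 1..genomeLen (1-based closed intervals)
bruteDepth <- function(peaks, genomeLen) {
    d <- integer(genomeLen)
    for (k in seq_along(peaks))
        d[start(peaks)[k]:end(peaks)[k]] <-
            d[start(peaks)[k]:end(peaks)[k]] + 1L
    d
}

# connected components of the pairwise-overlap graph (single chromosome);
# labels renumbered 1..n in order of leftmost member start
bruteClusterLabels <- function(peaks) {
    n <- length(peaks)
    s <- start(peaks); e <- end(peaks)
    adj <- outer(seq_len(n), seq_len(n),
                 function(i, j) s[i] <= e[j] & s[j] <= e[i])
    lab <- rep(NA_integer_, n)
    cur <- 0L
    for (i in seq_len(n)) {
        if (!is.na(lab[i])) next
        cur <- cur + 1L
        queue <- i
        lab[i] <- cur
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            nb <- which(adj[v, ] & is.na(lab))
            lab[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    first <- vapply(split(s, lab), min, 0)
    rk <- rank(first, ties.method = "first")  # renumber by leftmost start
    rk[lab]
}

# weighted-moment trim computed base by base; returns c(start1, end1)
bruteTrimInterval <- function(peaks, kSigma = 2) {
    s <- min(start(peaks)); e <- max(end(peaks))
    d <- bruteDepth(peaks, e)[s:e]
    bases <- (s:e)[d > 0]
    w <- d[d > 0]
    centers <- bases - 0.5                  # 0-based base centers
    mu <- sum(w * centers) / sum(w)
    sigma <- sqrt(sum(w * (centers - mu)^2) / sum(w))
    if (sigma == 0) return(c(s, e))
    s1 <- max(floor(mu - kSigma * sigma) + 1, s)
    e1 <- min(ceiling(mu + kSigma * sigma), e)
    if (s1 > e1) c(s, e) else c(s1, e1)
}

# partition equality up to relabeling
samePartition <- function(a, b) {
    identical(unname(split(seq_along(a), a)[order(!duplicated(a))]),
              unname(split(seq_along(b), b)[order(!duplicated(b))])) ||
        identical(lapply(unname(split(seq_along(a), a)), sort),
                  lapply(unname(split(seq_along(b), b)), sort))
}

writeLinesTmp <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# strong non-palindromic 8 bp test motif: near-deterministic columns
strongMotif <- function(total = 20) {
    cons <- c("A", "C", "G", "A", "T", "G", "G", "C")
    counts <- sapply(cons, function(b) {
        col <- rep(0, 4)
        names(col) <- c("A", "C", "G", "T")
        col[b] <- total
        col
    })
    colnames(counts) <- NULL
    motifMatrix("MTEST.1", counts, name = "testTF")
}
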