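# Allele-specific motif scoring: PFM -> log-odds conversion, relative
# scoring of sequence windows, and the created/disrupted/strengthened/
# weakened verdict for an allele pair.

.BASES <- c("A", "C", "G", "T")

#' Construct a MotifMatrix
#'
#' @param motifId identifier string.
#' @param counts numeric 4 x w matrix of base counts; rows are taken in
#'   A, C, G, T order when unnamed.
#' @param name TF name (defaults to motifId).
#' @return a \linkS4class{MotifMatrix}.
#' @export
motifMatrix <- function(motifId, counts, name = motifId) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts))) rownames(counts) <- .BASES
    new("MotifMatrix", motifId = motifId, name = name,
        counts = counts[.BASES, , drop = FALSE])
}

#' Consensus sequence of a PFM
#'
#' Per-column argmax base; ties resolved in A, C, G, T order.
#'
#' @param pfm a \linkS4class{MotifMatrix}.
#' @return character consensus string of length w.
#' @export
motifConsensus <- function(pfm) {
    paste(.BASES[apply(motifCounts(pfm), 2L, which.max)], collapse = "")
}

#' Convert a PFM to a log-odds scoring matrix
#'
#' Column j, base b gets
#' \code{log2((count[b,j] + pseudocount * background[b]) /
#' (colsum_j + pseudocount) / background[b])}, i.e. a background-distributed
#' pseudocount followed by the log odds against the background. The
#' columnwise minima and maxima are aggregated into the score range used by
#' \code{\link{relativeScore}}.
#'
#' @param pfm a \linkS4class{MotifMatrix}.
#' @param pseudocount positive total pseudocount (default 0.8).
#' @param background base composition in A, C, G, T order, summing to 1
#'   (default uniform).
#' @return a \linkS4class{LogOddsMatrix}.
#' @export
pfmToLogOdds <- function(pfm, pseudocount = 0.8,
                         background = rep(0.25, 4)) {
    stopifnot(is(pfm, "MotifMatrix"), pseudocount > 0,
              length(background) == 4L,
              isTRUE(all.equal(sum(background), 1)))
    cn <- motifCounts(pfm)
    csum <- colSums(cn)
    prob <- sweep(cn + pseudocount * background, 2L, csum + pseudocount, "/")
    vals <- log2(prob / background)
    dimnames(vals) <- dimnames(cn)
    new("LogOddsMatrix", motifId = pfm@motifId, name = pfm@name,
        values = vals,
        minScore = sum(apply(vals, 2L, min)),
        maxScore = sum(apply(vals, 2L, max)))
}

#' Relative score of sequence windows
#'
#' (raw - minScore) / (maxScore - minScore), in [0, 1]; 1 exactly for a
#' per-column argmax (consensus) window and 0 exactly for a per-column
#' argmin window. Windows containing a base outside A/C/G/T are skipped
#' (NA) with a notice.
#'
#' @param lom a \linkS4class{LogOddsMatrix}.
#' @param windows character vector of sequences, each of the motif width.
#' @return numeric vector of relative scores (NA for skipped windows).
#' @export
relativeScore <- function(lom, windows) {
    stopifnot(is(lom, "LogOddsMatrix"))
    w <- ncol(lom@values)
    stopifnot(all(nchar(windows) == w))
    vapply(windows, function(win) {
        idx <- match(strsplit(toupper(win), "")[[1L]], .BASES)
        if (anyNA(idx)) {
            message("relativeScore: window '", win,
                    "' contains an ambiguous base; skipped")
            return(NA_real_)
        }
        raw <- sum(lom@values[cbind(idx, seq_len(w))])
        (raw - lom@minScore) / (lom@maxScore - lom@minScore)
    }, numeric(1L), USE.NAMES = FALSE)
}

#' Construct an AlleleWindowPair
#'
#' @param snpId identifier.
#' @param seqRef,seqAlt equal-length sequences over A/C/G/T differing only
#'   at the variant base.
#' @param snpOffset 0-based index of the variant base.
#' @return an \linkS4class{AlleleWindowPair}.
#' @export
alleleWindowPair <- function(snpId, seqRef, seqAlt, snpOffset) {
    new("AlleleWindowPair", snpId = as.character(snpId),
        seqRef = toupper(seqRef), seqAlt = toupper(seqAlt),
        snpOffset = as.integer(snpOffset))
}

#' Extract allele windows around SNPs from a genome
#'
#' Cuts a window of \code{flank} bases either side of each SNP out of the
#' genome and substitutes each alternate allele, yielding one
#' \linkS4class{AlleleWindowPair} per (SNP, alt allele). SNPs whose stated
#' reference allele disagrees with the genome raise a warning (the genome
#' base is used). Windows are clipped at chromosome ends.
#'
#' @param snps GRanges with id, ref, alt metadata (see
#'   \code{\link{readSnps}}); alt-less SNPs are skipped.
#' @param genome a named \linkS4class{DNAStringSet} (e.g. from
#'   \code{Biostrings::readDNAStringSet}).
#' @param flank flank size in bp; must be at least max motif width - 1 for
#'   a complete scan.
#' @return list of \linkS4class{AlleleWindowPair}.
#' @export
extractAlleleWindows <- function(snps, genome, flank) {
    stopifnot(is(genome, "DNAStringSet"), flank >= 1)
    names(genome) <- sub("\\s.*$", "", names(genome))
    out <- list()
    for (k in seq_along(snps)) {
        chrom <- as.character(seqnames(snps)[k])
        if (!chrom %in% names(genome)) {
            warning("SNP ", mcols(snps)$id[k], ": chromosome ", chrom,
                    " absent from genome; skipped")
            next
        }
        chromSeq <- genome[[chrom]]
        pos <- start(snps)[k]
        lo <- max(1L, pos - as.integer(flank))
        hi <- min(length(chromSeq), pos + as.integer(flank))
        refWin <- toupper(as.character(subseq(chromSeq, lo, hi)))
        off <- pos - lo
        stated <- mcols(snps)$ref[k]
        genomeBase <- substr(refWin, off + 1L, off + 1L)
        if (!is.na(stated) && nzchar(stated) &&
            toupper(stated) != genomeBase)
            warning("SNP ", mcols(snps)$id[k], ": stated ref '", stated,
                    "' differs from genome base '", genomeBase, "'")
        alts <- mcols(snps)$alt[[k]]
        alts <- alts[nchar(alts) == 1L & toupper(alts) %in% .BASES]
        for (a in alts) {
            altWin <- refWin
            substr(altWin, off + 1L, off + 1L) <- toupper(a)
            out[[length(out) + 1L]] <- alleleWindowPair(
                mcols(snps)$id[k], refWin, altWin, off)
        }
    }
    out
}

.revcomp <- function(x) as.character(reverseComplement(DNAString(x)))

#' Allele-specific motif impact calls
#'
#' Scores every window overlapping the variant base of both allelic
#' sequences, on both strands (reverse-complement scanning), against each
#' motif, and classifies per (motif, strand, offset):
#' \itemize{
#'   \item \emph{created}: alt >= threshold > ref
#'   \item \emph{disrupted}: ref >= threshold > alt
#'   \item \emph{strengthened}/\emph{weakened}: both >= threshold and the
#'     relative scores differ by more than \code{delta}
#' }
#' Pairs below threshold in both alleles, or above threshold with a score
#' difference of at most \code{delta}, are omitted. A no-op pair
#' (identical sequences) yields an empty call set.
#'
#' @param pair an \linkS4class{AlleleWindowPair}.
#' @param motifs list of \linkS4class{LogOddsMatrix} (a single matrix is
#'   accepted).
#' @param threshold relative-score presence cutoff (default 0.80).
#' @param delta minimum relative-score difference to call a present motif
#'   strengthened/weakened (default 0.05).
#' @return data.frame with columns snp_id, motif_id, strand, offset
#'   (0-based window start in the allele sequence), score_ref, score_alt,
#'   category; sorted by motif_id, offset, strand.
#' @export
alleleImpact <- function(pair, motifs, threshold = 0.80, delta = 0.05) {
    stopifnot(is(pair, "AlleleWindowPair"))
    if (is(motifs, "LogOddsMatrix")) motifs <- list(motifs)
    empty <- data.frame(snp_id = character(0), motif_id = character(0),
                        strand = character(0), offset = integer(0),
                        score_ref = numeric(0), score_alt = numeric(0),
                        category = character(0))
    if (pair@seqRef == pair@seqAlt) return(empty)
    len <- nchar(pair@seqRef)
    rows <- list()
    for (lom in motifs) {
        w <- ncol(lom@values)
        if (w > len) next
        o0 <- max(0L, pair@snpOffset - w + 1L)
        o1 <- min(len - w, pair@snpOffset)
        if (o0 > o1) next
        for (off in o0:o1) {
            winR <- substr(pair@seqRef, off + 1L, off + w)
            winA <- substr(pair@seqAlt, off + 1L, off + w)
            for (std in c("+", "-")) {
                sr <- if (std == "+") relativeScore(lom, winR)
                      else relativeScore(lom, .revcomp(winR))
                sa <- if (std == "+") relativeScore(lom, winA)
                      else relativeScore(lom, .revcomp(winA))
                cat <- .classifyImpact(sr, sa, threshold, delta)
                if (!is.na(cat))
                    rows[[length(rows) + 1L]] <- data.frame(
                        snp_id = pair@snpId, motif_id = lom@motifId,
                        strand = std, offset = off, score_ref = sr,
                        score_alt = sa, category = cat)
            }
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out <- out[order(out$motif_id, out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.classifyImpact <- function(sr, sa, threshold, delta) {
    if (is.na(sr) || is.na(sa)) return(NA_character_)
    if (sa >= threshold && sr < threshold) return("created")
    if (sr >= threshold && sa < threshold) return("disrupted")
    if (sr >= threshold && sa >= threshold && abs(sa - sr) > delta)
        return(if (sa > sr) "strengthened" else "weakened")
    NA_character_
}
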