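# Readers and writers for the external formats the pipeline touches.
# Everything is converted at the boundary to GRanges conventions (1-based,
# closed); BED and "chr:start-end" inputs are 0-based half-open / 1-based
# inclusive respectively, and VCF is 1-based. Output columns named pos0 are
# 0-based positions.

.isComment <- function(lines) {
    grepl("^\\s*$", lines) | grepl("^(#|track\\b|browser\\b)", lines)
}

.splitTab <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.asCoord <- function(x) suppressWarnings(as.numeric(x))

#' Read a TF-binding peak track (BED4+)
#'
#' Parses a BED-like ChIP-seq peak track in the layout of the ENCODE
#' clustered TF-binding track: chrom, start, end, factor name and an optional
#' score, followed by any number of extra columns which are preserved
#' verbatim but not interpreted.
#'
#' @param path path to a tab-separated BED4+ file. Coordinates are 0-based
#'   half-open (BED native) and are converted to 1-based closed GRanges.
#' @param dedupeByFactor if TRUE, drop records duplicated in
#'   (chrom, start, end, factor). Defaults to FALSE: the method counts peak
#'   records, not unique factors.
#' @return GRanges in file order with metadata columns \code{factor},
#'   \code{score} (NA when absent) and, when extra columns exist,
#'   \code{extraFields} (the joined remainder of each line).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tCTCF\t900", f)
#' readTfbsClusters(f)
#' @export
readTfbsClusters <- function(path, dedupeByFactor = FALSE) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    keep <- !.isComment(lines)
    lineNo <- which(keep)
    if (!length(lineNo))
        return(GRanges(factor = character(0), score = numeric(0)))
    fields <- .splitTab(lines[keep])
    nf <- lengths(fields)
    if (any(nf < 4L))
        stop("parse error at line ", lineNo[which(nf < 4L)[1L]],
             ": expected >= 4 tab-separated fields")
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- .asCoord(vapply(fields, `[`, "", 2L))
    end0 <- .asCoord(vapply(fields, `[`, "", 3L))
    bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
    if (length(bad))
        stop("parse error at line ", lineNo[bad[1L]],
             ": non-integer coordinates")
    bad <- which(start0 >= end0 | start0 < 0)
    if (length(bad))
        stop("parse error at line ", lineNo[bad[1L]],
             ": require 0 <= start < end")
    fac <- vapply(fields, `[`, "", 4L)
    if (any(!nzchar(fac)))
        stop("parse error at line ", lineNo[which(!nzchar(fac))[1L]],
             ": empty factor name")
    score <- rep(NA_real_, length(fields))
    has5 <- nf >= 5L
    score[has5] <- .asCoord(vapply(fields[has5], `[`, "", 5L))
    gr <- GRanges(chrom, IRanges(start0 + 1, end0),
                  factor = fac, score = score, sourceLine = lineNo)
    if (any(nf > 5L)) {
        extra <- vapply(fields, function(f)
            if (length(f) > 5L) paste(f[-(1:5)], collapse = "\t") else "",
            "")
        mcols(gr)$extraFields <- extra
    }
    if (dedupeByFactor) {
        key <- paste(chrom, start0, end0, fac, sep = "\r")
        gr <- gr[!duplicated(key)]
    }
    gr
}

#' Read SNPs from BED, VCF or a tabular association file
#'
#' All positions are normalized to the internal 1-based convention
#' (\code{start(x)}); VCF is read through \pkg{VariantAnnotation}. The
#' tabular dialect expects a header declaring columns among
#' \code{id, chrom, pos0, pos1, ref, alt, p, OR} (case-insensitive;
#' \code{p_value}/\code{pvalue} and \code{odds_ratio}/\code{oddsratio} are
#' accepted synonyms); the separator (tab or comma) is sniffed from the
#' header line.
#'
#' @param path input file.
#' @param dialect one of "bed", "vcf", "tsv".
#' @return GRanges of width-1 positions with metadata columns \code{id},
#'   \code{ref} (NA when unknown), \code{alt}
#'   (\linkS4class{CharacterList}, possibly empty), \code{pValue} and
#'   \code{oddsRatio}. Duplicate ids raise a warning; both records are kept.
#' @export
readSnps <- function(path, dialect = c("bed", "vcf", "tsv")) {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    snps <- switch(dialect,
        bed = .readSnpsBed(path),
        vcf = .readSnpsVcf(path),
        tsv = .readSnpsTsv(path))
    dup <- duplicated(mcols(snps)$id)
    if (any(dup))
        warning("duplicate SNP ids kept: ",
                paste(unique(mcols(snps)$id[dup]), collapse = ", "))
    snps
}

.emptyAlt <- function(n) IRanges::CharacterList(rep(list(character(0)), n))

.snpGRanges <- function(chrom, pos1, id, ref = NULL, alt = NULL,
                        pValue = NULL, oddsRatio = NULL) {
    n <- length(pos1)
    if (any(pos1 < 1))
        stop("coordinate underflow: position < 0 after conversion")
    gr <- GRanges(chrom, IRanges(pos1, width = 1L))
    mcols(gr)$id <- as.character(id)
    mcols(gr)$ref <- if (is.null(ref)) rep(NA_character_, n)
                     else as.character(ref)
    mcols(gr)$alt <- if (is.null(alt)) .emptyAlt(n)
                     else IRanges::CharacterList(alt)
    mcols(gr)$pValue <- if (is.null(pValue)) rep(NA_real_, n)
                        else as.numeric(pValue)
    mcols(gr)$oddsRatio <- if (is.null(oddsRatio)) rep(NA_real_, n)
                           else as.numeric(oddsRatio)
    gr
}

.readSnpsBed <- function(path) {
    lines <- readLines(path)
    keep <- !.isComment(lines)
    lineNo <- which(keep)
    if (!length(lineNo)) return(.snpGRanges(character(0), integer(0),
                                            character(0)))
    fields <- .splitTab(lines[keep])
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("parse error at line ", lineNo[which(nf < 3L)[1L]],
             ": expected >= 3 BED fields")
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- .asCoord(vapply(fields, `[`, "", 2L))
    if (anyNA(start0))
        stop("parse error at line ", lineNo[which(is.na(start0))[1L]],
             ": non-integer coordinate")
    id <- ifelse(nf >= 4L, vapply(fields, `[`, "", 4L), NA)
    id[is.na(id) | !nzchar(id)] <-
        paste0("snp", which(is.na(id) | !nzchar(id)))
    .snpGRanges(chrom, start0 + 1, id)
}

.readSnpsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- IRanges::CharacterList(lapply(VariantAnnotation::alt(vcf),
                                         as.character))
    .snpGRanges(as.character(seqnames(rr)), start(rr),
                names(rr), as.character(VariantAnnotation::ref(vcf)), alt)
}

.readSnpsTsv <- function(path) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    tab <- read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
    cn <- tolower(colnames(tab))
    pick <- function(...) {
        hit <- which(cn %in% c(...))
        if (length(hit)) tab[[hit[1L]]] else NULL
    }
    chrom <- pick("chrom", "chr")
    if (is.null(chrom)) stop("tsv dialect requires a chrom column")
    pos1 <- pick("pos1")
    if (is.null(pos1)) {
        pos0 <- pick("pos0", "pos")
        if (is.null(pos0)) stop("tsv dialect requires a pos0 or pos1 column")
        pos1 <- as.numeric(pos0) + 1
    }
    id <- pick("id", "snp", "rsid")
    if (is.null(id)) id <- paste0("snp", seq_len(nrow(tab)))
    alt <- pick("alt")
    alt <- if (is.null(alt)) NULL else strsplit(as.character(alt), ",")
    .snpGRanges(chrom, as.numeric(pos1), id,
                ref = pick("ref"), alt = alt,
                pValue = pick("p", "p_value", "pvalue", "p.value"),
                oddsRatio = pick("or", "odds_ratio", "oddsratio"))
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR PFM text layout: a \code{>ID name} header followed by
#' four count rows. Rows may be bracketed (\code{A [ 4 19 0 ]}) or bare
#' whitespace-separated numbers; when base labels are present they are used,
#' otherwise A, C, G, T order is assumed.
#'
#' @param path path to the PFM file; may contain multiple records.
#' @return a list of \linkS4class{MotifMatrix}, ids preserved in file order.
#' @export
readJasparPfm <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*$", lines)]
    starts <- grep("^>", lines)
    if (!length(starts)) {
        if (!length(lines)) return(list())
        stop("missing '>' header in PFM file")
    }
    if (starts[1L] != 1L) stop("counts before the first '>' header")
    ends <- c(starts[-1L] - 1L, length(lines))
    motifs <- vector("list", length(starts))
    for (k in seq_along(starts)) {
        hdr <- sub("^>\\s*", "", lines[starts[k]])
        toks <- strsplit(hdr, "\\s+")[[1L]]
        id <- toks[1L]
        nm <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
        body <- lines[(starts[k] + 1L):ends[k]]
        if (length(body) != 4L)
            stop("motif ", id, ": expected 4 count rows, got ", length(body))
        rows <- lapply(body, .parsePfmRow)
        bases <- vapply(rows, `[[`, "", "base")
        counts <- lapply(rows, `[[`, "counts")
        w <- unique(lengths(counts))
        if (length(w) != 1L)
            stop("motif ", id, ": count rows have unequal length")
        mat <- do.call(rbind, counts)
        rownames(mat) <- if (all(bases %in% c("A", "C", "G", "T")) &&
                             !anyDuplicated(bases)) bases
                         else c("A", "C", "G", "T")
        mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
        if (any(mat < 0)) stop("motif ", id, ": negative counts")
        motifs[[k]] <- new("MotifMatrix", motifId = id, name = nm,
                           counts = mat)
    }
    motifs
}

.parsePfmRow <- function(line) {
    toks <- strsplit(trimws(chartr("[]:", "   ", line)), "\\s+")[[1L]]
    base <- NA_character_
    if (length(toks) && toks[1L] %in%
        c("A", "C", "G", "T", "a", "c", "g", "t")) {
        base <- toupper(toks[1L])
        toks <- toks[-1L]
    }
    counts <- suppressWarnings(as.numeric(toks))
    if (!length(counts) || anyNA(counts))
        stop("unparseable PFM count row: ", line)
    list(base = base, counts = counts)
}

#' Read a two-column chromosome sizes file
#'
#' @param path tab-separated file with columns chrom and length.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "length"),
                      stringsAsFactors = FALSE)
    if (any(tab$length <= 0) || anyNA(tab$length))
        stop("chromosome lengths must be positive")
    setNames(as.numeric(tab$length), tab$chrom)
}

#' Read a blacklist of excluded regions
#'
#' Accepts BED lines (0-based half-open) or region strings of the form
#' \code{chr6:29,909,708-31,325,212} (1-based inclusive, commas allowed),
#' one per line; both are converted to the internal convention.
#'
#' @param path input file; empty files yield an empty GRanges.
#' @return GRanges of regions to exclude.
#' @export
readBlacklist <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[!.isComment(lines)]
    if (!length(lines)) return(GRanges())
    parseOne <- function(line) {
        if (grepl("\t", line)) {
            f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
            if (length(f) < 3L) stop("unparseable blacklist line: ", line)
            s0 <- .asCoord(f[2L]); e0 <- .asCoord(f[3L])
            if (anyNA(c(s0, e0)) || s0 >= e0)
                stop("unparseable blacklist line: ", line)
            GRanges(f[1L], IRanges(s0 + 1, e0))
        } else {
            m <- regmatches(line,
                regexec("^\\s*(\\S+):([0-9,]+)-([0-9,]+)\\s*$", line))[[1L]]
            if (length(m) != 4L)
                stop("unparseable region string: ", line)
            s1 <- as.numeric(gsub(",", "", m[3L]))
            e1 <- as.numeric(gsub(",", "", m[4L]))
            if (is.na(s1) || is.na(e1) || s1 > e1)
                stop("unparseable region string: ", line)
            GRanges(m[2L], IRanges(s1, e1))
        }
    }
    do.call(c, lapply(lines, parseOne))
}

#' Write OTFRs as BED6 (+ true peak count)
#'
#' Output columns: chrom, start (0-based), end, name \code{OTFR_<clusterId>},
#' score = peak count clamped to 1000 for BED validity, strand ".", and the
#' unclamped peak count as a 7th column.
#'
#' @param otfrs an \linkS4class{OTFRSet} (or GRanges with clusterId and
#'   peakCount metadata).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOtfrBed <- function(otfrs, path) {
    gr <- if (is(otfrs, "OTFRSet")) otfrRanges(otfrs) else otfrs
    cnt <- mcols(gr)$peakCount
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = paste0("OTFR_", mcols(gr)$clusterId),
                      score = pmin(cnt, 1000L), strand = ".",
                      peakCount = cnt)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read back an OTFR BED file
#'
#' @param path a file written by \code{\link{writeOtfrBed}} (plain BED3+ is
#'   accepted; peak counts are taken from column 7 when present, else from
#'   the score column).
#' @return GRanges with metadata columns clusterId and peakCount.
#' @export
readOtfrBed <- function(path) {
    lines <- readLines(path)
    keep <- !.isComment(lines)
    if (!any(keep))
        return(GRanges(clusterId = integer(0), peakCount = integer(0)))
    fields <- .splitTab(lines[keep])
    nf <- lengths(fields)
    if (any(nf < 3L)) stop("expected >= 3 BED fields")
    chrom <- vapply(fields, `[`, "", 1L)
    s0 <- .asCoord(vapply(fields, `[`, "", 2L))
    e0 <- .asCoord(vapply(fields, `[`, "", 3L))
    gr <- GRanges(chrom, IRanges(s0 + 1, e0))
    id <- seq_along(gr)
    if (all(nf >= 4L)) {
        nm <- vapply(fields, `[`, "", 4L)
        parsed <- suppressWarnings(as.integer(sub("^OTFR_", "", nm)))
        if (!anyNA(parsed)) id <- parsed
    }
    cnt <- if (all(nf >= 7L))
        as.integer(.asCoord(vapply(fields, `[`, "", 7L)))
    else if (all(nf >= 5L))
        as.integer(.asCoord(vapply(fields, `[`, "", 5L)))
    else rep(NA_integer_, length(gr))
    mcols(gr)$clusterId <- id
    mcols(gr)$peakCount <- cnt
    gr
}

#' Write peaks as BED5
#'
#' @param peaks GRanges with factor (and optionally score) metadata.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeaksBed <- function(peaks, path) {
    score <- mcols(peaks)$score
    if (is.null(score)) score <- rep(0, length(peaks))
    score[is.na(score)] <- 0
    tab <- data.frame(chrom = as.character(seqnames(peaks)),
                      start = start(peaks) - 1L, end = end(peaks),
                      name = mcols(peaks)$factor, score = score)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write SNPs as BED4 or minimal sites-only VCF
#'
#' The BED form keeps positions and ids only; the VCF form also carries
#' ref/alt alleles (missing alleles written as N).
#'
#' @param snps GRanges as returned by \code{\link{readSnps}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSnpsBed <- function(snps, path) {
    tab <- data.frame(chrom = as.character(seqnames(snps)),
                      start = start(snps) - 1L, end = start(snps),
                      name = mcols(snps)$id)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeSnpsBed
#' @export
writeSnpsVcf <- function(snps, path) {
    ref <- mcols(snps)$ref
    ref[is.na(ref)] <- "N"
    alt <- vapply(mcols(snps)$alt, function(a)
        if (length(a)) paste(a, collapse = ",") else "N", "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=otfr", packageVersion("otfr")),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (length(snps))
        writeLines(paste(as.character(seqnames(snps)), start(snps),
                         mcols(snps)$id, ref, alt, ".", ".", ".",
                         sep = "\t"), con)
    invisible(path)
}
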