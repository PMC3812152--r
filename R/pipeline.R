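# End-to-end pipeline: peaks -> OTFR(i) -> SNP annotation -> enrichment
# curve with bootstrap -> ranked candidate rSNPs -> optional motif impact.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full regulatory-SNP detection pipeline
#'
#' Reads a peak track and a SNP set, builds OTFRs at \code{iMin}, annotates
#' every SNP with its peak depth and OTFR membership, computes the
#' enrichment curve over \code{iRange} with a bootstrap at each threshold,
#' and writes the candidate list: SNPs inside an OTFR at \code{iMin},
#' ranked by depth at the SNP (descending), then by cluster peak count.
#' When a PFM file and a FASTA genome are supplied, candidates additionally
#' get allele-specific motif-impact calls.
#'
#' Artifacts written to \code{outDir}: \code{otfr.bed},
#' \code{annotated_snps.tsv}, \code{enrichment.tsv}, \code{candidates.tsv},
#' optionally \code{impact.tsv}, and \code{run.log} with per-stage counts.
#' Any stage error aborts with a stage-named message and removes partial
#' outputs.
#'
#' @param peaksFile BED4+ peak track (see \code{\link{readTfbsClusters}}).
#' @param snpsFile SNP input file.
#' @param outDir output directory (created if needed).
#' @param snpDialect dialect of \code{snpsFile}: "bed", "vcf" or "tsv".
#' @param blacklistFile optional blacklist (regions to exclude).
#' @param chromSizesFile optional chrom.sizes; when given, the genome
#'   length G is the sum of the listed lengths instead of the 3e9 default.
#' @param pfmFile,fastaFile optional JASPAR PFM file and FASTA genome for
#'   the motif-impact stage.
#' @param iMin candidate threshold (default 7).
#' @param iRange thresholds for the enrichment curve (default 2:40).
#' @param trim,kSigma Gaussian trimming parameters.
#' @param bootstrap bootstrap iterations per curve point (default 500;
#'   0 disables the bootstrap columns).
#' @param seed master seed for all randomness.
#' @param ciLevel bootstrap confidence level (default 0.99).
#' @param pMax,orHigh,orLow,filterMode optional association filter applied
#'   to the SNPs before analysis (see \code{\link{filterAssociation}}).
#' @param motifThreshold,motifDelta motif-impact parameters.
#' @param motifFlank flank size for allele windows (default: max motif
#'   width - 1).
#' @param genomeLength genome length G when no chrom.sizes is given.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(peaksFile, snpsFile, outDir,
                        snpDialect = c("bed", "vcf", "tsv"),
                        blacklistFile = NULL, chromSizesFile = NULL,
                        pfmFile = NULL, fastaFile = NULL,
                        iMin = 7L, iRange = 2:40, trim = TRUE, kSigma = 2,
                        bootstrap = 500L, seed = 1L, ciLevel = 0.99,
                        pMax = NULL, orHigh = NULL, orLow = NULL,
                        filterMode = "both",
                        motifThreshold = 0.80, motifDelta = 0.05,
                        motifFlank = NULL, genomeLength = 3e9) {
    snpDialect <- match.arg(snpDialect)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    written <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(written))
    logLines <- c(sprintf("otfr %s", packageVersion("otfr")),
                  sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                  sprintf("seed %d", seed))
    note <- function(fmt, ...) logLines <<- c(logLines, sprintf(fmt, ...))

    peaks <- .stage("read-peaks", {
        if (!file.exists(peaksFile)) stop("missing peaks file: ", peaksFile)
        readTfbsClusters(peaksFile)
    })
    note("peaks read: %d", length(peaks))

    snps <- .stage("read-snps", {
        if (!file.exists(snpsFile)) stop("missing SNPs file: ", snpsFile)
        readSnps(snpsFile, dialect = snpDialect)
    })
    note("snps read: %d", length(snps))

    if (!is.null(blacklistFile)) {
        snps <- .stage("blacklist", {
            bl <- readBlacklist(blacklistFile)
            suppressMessages(subtractBlacklist(snps, bl))
        })
        note("snps after blacklist: %d", length(snps))
    }
    if (!is.null(pMax) || !is.null(orHigh) || !is.null(orLow)) {
        snps <- .stage("association-filter",
            suppressMessages(filterAssociation(snps, pMax = pMax,
                orHigh = orHigh, orLow = orLow, mode = filterMode)))
        note("snps after association filter: %d", length(snps))
    }
    if (!is.null(chromSizesFile)) {
        genomeLength <- .stage("chrom-sizes",
                               sum(readChromSizes(chromSizesFile)))
        note("genome length from chrom.sizes: %.0f", genomeLength)
    }

    clusters <- .stage("cluster-peaks", clusterPeaks(peaks))
    note("peak clusters: %d", length(clusterExtents(clusters)))

    otfrs <- .stage("build-otfr",
                    buildOtfr(clusters, iMin = iMin, trim = trim,
                              kSigma = kSigma))
    note("OTFR(i >= %d): %d regions, %.0f bp", iMin, length(otfrs),
         totalLength(otfrs))
    otfrBed <- file.path(outDir, "otfr.bed")
    written <- c(written, otfrBed)
    .stage("write-otfr", writeOtfrBed(otfrs, otfrBed))

    annot <- .stage("annotate-snps", annotateSnps(snps, peaks, otfrs))
    annotFile <- file.path(outDir, "annotated_snps.tsv")
    written <- c(written, annotFile)
    .stage("write-annotation",
           write.table(as.data.frame(annot), annotFile, sep = "\t",
                       quote = FALSE, row.names = FALSE))
    note("snps in OTFR(i >= %d): %d of %d", iMin, sum(annot$in_otfr),
         nrow(annot))

    curve <- .stage("enrichment-curve", {
        if (!length(snps)) stop("no SNPs left to analyze")
        cv <- enrichmentCurve(snps, clusters, iValues = iRange,
                              trim = trim, kSigma = kSigma,
                              genomeLength = genomeLength)
        if (bootstrap >= 2L) {
            boot <- lapply(seq_len(nrow(cv)), function(r) {
                ot <- buildOtfr(clusters, iMin = cv$i[r], trim = trim,
                                kSigma = kSigma)
                if (!length(ot))
                    return(data.frame(boot_mean = NA_real_,
                                      boot_sd = NA_real_,
                                      ci_low = NA_real_,
                                      ci_high = NA_real_,
                                      chi2_p = NA_real_))
                bs <- bootstrapEnrichment(snps, ot, B = bootstrap,
                                          seed = seed + cv$i[r],
                                          ciLevel = ciLevel,
                                          genomeLength = genomeLength)
                data.frame(boot_mean = bs@mean, boot_sd = bs@sd,
                           ci_low = bs@ciLow, ci_high = bs@ciHigh,
                           chi2_p = bs@chi2P)
            })
            cv <- cbind(cv, do.call(rbind, boot))
        }
        cv
    })
    curveFile <- file.path(outDir, "enrichment.tsv")
    written <- c(written, curveFile)
    write.table(curve, curveFile, sep = "\t", quote = FALSE,
                row.names = FALSE)

    cand <- .stage("candidates", {
        x <- as.data.frame(annot[annot$in_otfr, , drop = FALSE])
        x[order(-x$depth_at_snp, -x$cluster_peak_count, x$snp_id), ,
          drop = FALSE]
    })
    candFile <- file.path(outDir, "candidates.tsv")
    written <- c(written, candFile)
    write.table(cand, candFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("candidates: %d", nrow(cand))

    paths <- list(otfr = otfrBed, annotation = annotFile,
                  enrichment = curveFile, candidates = candFile)

    if (!is.null(pfmFile) && !is.null(fastaFile)) {
        impact <- .stage("motif-impact", {
            motifs <- lapply(readJasparPfm(pfmFile), pfmToLogOdds)
            if (!length(motifs)) stop("no motifs in ", pfmFile)
            flank <- if (is.null(motifFlank))
                max(vapply(motifs, function(m) ncol(m@values), 0L)) - 1L
            else as.integer(motifFlank)
            genome <- Biostrings::readDNAStringSet(fastaFile)
            candSnps <- snps[mcols(snps)$id %in% cand$snp_id]
            pairs <- suppressWarnings(
                extractAlleleWindows(candSnps, genome, flank))
            calls <- lapply(pairs, alleleImpact, motifs = motifs,
                            threshold = motifThreshold, delta = motifDelta)
            do.call(rbind, c(list(alleleImpact(
                alleleWindowPair("none", "A", "A", 0), motifs)), calls))
        })
        impactFile <- file.path(outDir, "impact.tsv")
        written <- c(written, impactFile)
        write.table(impact, impactFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        note("motif impact calls: %d", nrow(impact))
        paths$impact <- impactFile
    }

    logFile <- file.path(outDir, "run.log")
    written <- c(written, logFile)
    writeLines(logLines, logFile)
    paths$log <- logFile
    ok <- TRUE
    invisible(paths)
}
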