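# The enrichment statistic E(i), its bootstrap uncertainty, the normality
# check of the bootstrap distribution, and association-based SNP filtering.

#' Enrichment of a SNP sample in OTFRs
#'
#' E = P*/P, where P* = nIn/nTotal is the observed probability that a SNP of
#' the sample falls inside an OTFR and P = L/G is the probability expected
#' under a uniform distribution over a genome of length G (default
#' 3e9 bp). Equivalently E = (nIn/nTotal) * G/L.
#'
#' @param nIn number of SNPs inside OTFRs.
#' @param nTotal total SNPs in the sample (> 0).
#' @param otfrLength total OTFR length L in bp (0 < L <= G).
#' @param genomeLength genome length G in bp (default 3e9).
#' @param iMin optional threshold i the OTFRs were built at (bookkeeping).
#' @return an \linkS4class{EnrichmentResult}.
#' @examples
#' eValue(enrichment(10, 50, 100, 1000))  # (0.2)/(0.1) = 2
#' @export
enrichment <- function(nIn, nTotal, otfrLength, genomeLength = 3e9,
                       iMin = NA_integer_) {
    if (nTotal <= 0)
        stop("enrichment is undefined for an empty SNP sample (nTotal = 0)")
    if (otfrLength <= 0)
        stop("enrichment is undefined for zero total OTFR length")
    if (otfrLength > genomeLength)
        stop("otfrLength must not exceed genomeLength")
    if (nIn < 0 || nIn > nTotal)
        stop("need 0 <= nIn <= nTotal")
    pS <- nIn / nTotal
    pE <- otfrLength / genomeLength
    new("EnrichmentResult", iMin = as.integer(iMin), nIn = as.integer(nIn),
        nTotal = as.integer(nTotal), otfrLength = as.numeric(otfrLength),
        genomeLength = as.numeric(genomeLength), pStar = pS, pExp = pE,
        eValue = pS / pE)
}

#' Enrichment as a function of the peak-count threshold i
#'
#' Computes E(i) for a series of thresholds from a single clustering pass:
#' the trimmed region of each cluster is computed once and clusters are
#' filtered by peak count per i, so regions are nested across thresholds.
#'
#' @param snps GRanges of SNP positions.
#' @param clusters a \linkS4class{PeakClusters} (or GRanges of peaks).
#' @param iValues integer thresholds, each >= 2.
#' @param trim,kSigma trimming parameters, see \code{\link{buildOtfr}}.
#' @param genomeLength genome length G (default 3e9).
#' @return data.frame with columns i, n_in, n_total, L, G, e_value.
#' @export
enrichmentCurve <- function(snps, clusters, iValues = 2:40, trim = TRUE,
                            kSigma = 2, genomeLength = 3e9) {
    stopifnot(all(iValues >= 2))
    if (!is(clusters, "PeakClusters")) clusters <- clusterPeaks(clusters)
    regions <- .clusterRegions(clusters, trim = trim, kSigma = kSigma)
    cnt <- mcols(clusterExtents(clusters))$peakCount
    hit <- findOverlaps(granges(snps), regions, select = "first",
                        ignore.strand = TRUE)
    w <- as.numeric(width(regions))
    res <- lapply(iValues, function(i) {
        keep <- cnt >= i
        L <- sum(w[keep])
        nIn <- sum(!is.na(hit) & keep[ifelse(is.na(hit), 1L, hit)])
        data.frame(i = i, n_in = nIn, n_total = length(snps), L = L,
                   G = genomeLength,
                   e_value = if (L > 0)
                       (nIn / length(snps)) * genomeLength / L
                   else NA_real_)
    })
    do.call(rbind, res)
}

#' Bootstrap uncertainty of E(i)
#'
#' Each of B iterations resamples the SNP list with replacement and the
#' OTFR region list with replacement, both at their original sizes.
#' Duplicated regions count with multiplicity: the resampled total length
#' L* sums region widths as drawn, and n_in* counts each resampled SNP once
#' per draw of its containing region. E* = (n_in*/n) * G/L* is recorded per
#' iteration; the summary reports the mean, population standard deviation,
#' a normal-approximation confidence interval (mean +/- z * sd) and a
#' Pearson chi-squared test of normality of the B values.
#'
#' @param snps GRanges of SNP positions (non-empty).
#' @param otfrs an \linkS4class{OTFRSet} or GRanges of disjoint regions
#'   (non-empty).
#' @param B number of bootstrap iterations (default 500, >= 2).
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param ciLevel confidence level (default 0.99).
#' @param genomeLength genome length G (default 3e9).
#' @param ciType "normal" (default) for the symmetric mean +/- z * sd
#'   interval, or "percentile" for empirical quantiles of the B values.
#' @return a \linkS4class{BootstrapSummary}.
#' @export
bootstrapEnrichment <- function(snps, otfrs, B = 500L, seed = 1L,
                                ciLevel = 0.99, genomeLength = 3e9,
                                ciType = c("normal", "percentile")) {
    ciType <- match.arg(ciType)
    regions <- if (is(otfrs, "OTFRSet")) otfrRanges(otfrs) else otfrs
    stopifnot(B >= 2L, length(snps) >= 1L, length(regions) >= 1L)
    n <- length(snps)
    nR <- length(regions)
    w <- as.numeric(width(regions))
    regOfSnp <- findOverlaps(granges(snps), regions, select = "first",
                             ignore.strand = TRUE)
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    e <- numeric(B)
    for (b in seq_len(B)) {
        si <- sample.int(n, n, replace = TRUE)
        ri <- sample.int(nR, nR, replace = TRUE)
        perRegion <- tabulate(regOfSnp[si], nbins = nR)
        mult <- tabulate(ri, nbins = nR)
        Lstar <- sum(mult * w)
        e[b] <- (sum(mult * perRegion) / n) * genomeLength / Lstar
    }
    m <- mean(e)
    s <- sqrt(mean((e - m)^2))
    if (ciType == "normal") {
        z <- qnorm(1 - (1 - ciLevel) / 2)
        ci <- c(m - z * s, m + z * s)
    } else {
        ci <- unname(stats::quantile(e, c((1 - ciLevel) / 2,
                                          1 - (1 - ciLevel) / 2)))
    }
    chi <- if (B >= 50L && s > 0) normalityChi2(e)
           else list(statistic = NA_real_, df = NA_integer_,
                     p.value = NA_real_)
    new("BootstrapSummary", nIterations = as.integer(B),
        seed = as.integer(seed), values = e, mean = m, sd = s,
        ciLevel = ciLevel, ciLow = ci[1L], ciHigh = ci[2L],
        chi2Stat = chi$statistic, chi2Df = as.integer(chi$df),
        chi2P = chi$p.value)
}

#' Pearson chi-squared test of normality
#'
#' Fits a normal distribution by its sample mean and standard deviation,
#' bins the data into k equiprobable bins under the fitted normal, and
#' computes the Pearson statistic sum((O - E)^2 / E) on k - 3 degrees of
#' freedom (two estimated parameters plus the usual constraint).
#'
#' @param values numeric vector, length >= 50.
#' @param bins number of equiprobable bins (default 10).
#' @return list(statistic, df, p.value); p.value is the upper-tail
#'   chi-squared probability.
#' @export
normalityChi2 <- function(values, bins = 10L) {
    if (length(values) < 50L)
        stop("normalityChi2 needs at least 50 values")
    m <- mean(values)
    s <- sd(values)
    if (s == 0) stop("degenerate distribution: sd = 0")
    breaks <- qnorm(seq(0, 1, length.out = bins + 1L), mean = m, sd = s)
    obs <- tabulate(findInterval(values, breaks[-c(1L, bins + 1L)]) + 1L,
                    nbins = bins)
    expd <- length(values) / bins
    stat <- sum((obs - expd)^2 / expd)
    df <- bins - 3L
    list(statistic = stat, df = df,
         p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Filter SNPs by association statistics
#'
#' Reproduces the GWAS-catalog filters: keep SNPs with association p-value
#' strictly below \code{pMax} ("p_only"), with odds ratio strictly above
#' \code{orHigh} or strictly below \code{orLow} ("or_only"), or satisfying
#' both ("both"). Records lacking a filtered field are dropped, with the
#' count reported via \code{message()}.
#'
#' @param snps GRanges with pValue and/or oddsRatio metadata
#'   (see \code{\link{readSnps}}).
#' @param pMax p-value cutoff, e.g. 1e-7.
#' @param orHigh,orLow odds-ratio cutoffs, e.g. 3 and 0.33
#'   (orLow < 1 < orHigh).
#' @param mode which criteria to combine.
#' @return the retained SNPs.
#' @export
filterAssociation <- function(snps, pMax = NULL, orHigh = NULL,
                              orLow = NULL,
                              mode = c("both", "p_only", "or_only")) {
    mode <- match.arg(mode)
    useP <- mode %in% c("both", "p_only")
    useOr <- mode %in% c("both", "or_only")
    if (useP && is.null(pMax))
        stop("mode '", mode, "' requires pMax")
    if (useOr && (is.null(orHigh) || is.null(orLow)))
        stop("mode '", mode, "' requires orHigh and orLow")
    if (useOr && !(orLow < 1 && 1 < orHigh))
        stop("need orLow < 1 < orHigh")
    keep <- rep(TRUE, length(snps))
    dropped <- 0L
    if (useP) {
        p <- mcols(snps)$pValue
        miss <- is.na(p)
        dropped <- dropped + sum(miss & keep)
        keep <- keep & !miss & p < pMax
    }
    if (useOr) {
        or <- mcols(snps)$oddsRatio
        miss <- is.na(or)
        dropped <- dropped + sum(miss & keep)
        keep <- keep & !miss & (or > orHigh | or < orLow)
    }
    if (dropped > 0L)
        message("filterAssociation: dropped ", dropped,
                " records lacking the filtered field")
    snps[keep]
}
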