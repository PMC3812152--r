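---
title: "Methods: OTFR construction, enrichment statistics and motif impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTFR construction, enrichment statistics and motif impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otfr)
library(GenomicRanges)
```

# The model

`otfr` rests on one assumption: genomic regions where ChIP-seq peaks for
many different transcription factors pile up are regulatory, so a variant
inside such a region is more likely than a random variant to perturb
transcription. The package turns that assumption into three computable
objects.

**OTFRs.** Peaks are grouped by single-linkage overlap: two peaks belong
to the same cluster when they share at least one base, directly or through
intermediate peaks. Abutting intervals (`end == start` in half-open terms)
do *not* overlap — this is a convention, applied consistently and tested.
A cluster with at least `iMin` member peaks becomes an overlapping
TF-binding region, OTFR(i). The threshold `i` counts *member peaks of the
cluster*, not the pointwise depth: in the depth/count annotation pairs the
package reports per SNP (e.g. `4/33`), the denominator is constant across
all SNPs of one region, which is only consistent with a cluster-level
count. Pointwise depth at the SNP is the numerator and is reported
separately by `annotateSnps()`. For the stricter reading — only bases
covered by at least `i` peaks simultaneously —
`buildOtfr(countMode = "pointwise")` thresholds the depth profile
directly; those regions are already density-defined, so no Gaussian
trimming is applied to them.

**Gaussian trimming.** Cluster extents are ragged: a long straggler peak
can drag the extent far from where binding concentrates. The peak density
of a cluster is therefore approximated by a normal distribution and only
the central `kSigma = 2` standard deviations (about 95% of the density)
are kept, intersected with the extent. "Density" is made precise as
coverage: each covered base contributes its center coordinate with weight
equal to the number of peaks covering it, and μ and σ are the weighted
first and second moments, computed in closed form per constant-depth
segment (no per-base loops). For five identical peaks on a 100 bp
interval the weights are uniform and σ is the discrete-uniform closed form
`sqrt((100^2 - 1)/12) ≈ 28.861`, which the test suite checks to 1e-9.
Degenerate clusters (σ = 0, e.g. a single base) and empty intersections
fall back to the untrimmed extent. Because trimming depends only on the
cluster, OTFR(i) regions are *nested* across thresholds: every OTFR(i+1)
region is exactly the OTFR(i) region of the same cluster.

**Enrichment.** For a SNP sample, `E(i) = P*/P` with `P* = n_in/n_total`
(observed in-OTFR fraction) and `P = L/G` (expected fraction under a
uniform genomic distribution; `L` total OTFR length, `G` genome length).
`E` is dimensionless and invariant under rescaling all coordinates and
`G` by a common factor. `E` is undefined — an error, not 0 or NaN — when
the sample is empty or `L = 0`.

# Bootstrap uncertainty

`bootstrapEnrichment()` resamples *both* sides: each of `B` iterations
draws the SNP list with replacement and the OTFR region list with
replacement, each at its original size. Multiplicity is accounted
consistently: a region drawn twice contributes its width twice to `L*` and
its SNPs twice to `n_in*`. This keeps `E*` unbiased under the null, which
the calibration tests verify (uniform SNPs give `|E - 1|` within 3
bootstrap SDs across thresholds and seeds). The summary reports the mean
and *population* SD of the `B` values and a symmetric
normal-approximation interval `mean ± z·sd` (default `ciLevel = 0.99`),
matching the symmetric ±-style reporting this kind of analysis uses.
Percentile intervals are available via `ciType = "percentile"` but are
not the default: the bootstrap distribution is itself checked for
normality (below), and a symmetric interval is what the normality check
licenses.

Randomness is serial and single-stream: one `set.seed(seed)` governs an
entire bootstrap call, and the caller's RNG state is restored afterwards.
Identical inputs and seed give byte-identical summaries.

**Normality check.** Pearson's χ² against the fitted normal: the sample
mean and SD define `N(m, s)`, the data are binned into `k = 10`
equiprobable bins under that normal, and the statistic `Σ(O − E)²/E` is
referred to χ² with `df = k − 3` (two estimated parameters). The binning
and df are the textbook construction; neither is dictated by the method
itself, so both are arguments. One caveat is worth stating: with
parameters estimated from the ungrouped sample, the true null law lies
between χ²(k−3) and χ²(k−1) (Chernoff–Lehmann), so the test with
`df = k − 3` over-rejects mildly — at the 5% level roughly 8% of truly
normal samples are flagged. The test suite asserts the calibration at the
level the construction attains. `sd = 0` input is a degeneracy error, and
fewer than 50 values are refused.

# Association filtering and blacklisting

`filterAssociation()` mirrors the usual GWAS-catalog refinements: keep
SNPs with association p-value strictly below a cutoff (e.g. `1e-7`),
and/or odds ratio strictly outside `[orLow, orHigh]` (e.g. `OR > 3` or
`OR < 0.33`); `mode = "both"` intersects the two. Strict inequalities are
deliberate ("below", ">", "<"). Records lacking a filtered field cannot
satisfy a strict criterion and are dropped, with the count reported.
`subtractBlacklist()` removes SNPs by point containment; the canonical use
is the MHC region (`chr6:29,909,708-31,325,212`, 1-based), whose dense
genotyping otherwise inflates low-threshold enrichment.

# Motif impact

PFMs are converted to log-odds with a total pseudocount of 0.8
distributed by the background composition (uniform by default; both are
arguments):

```
value[b, j] = log2( (count[b,j] + 0.8 * bg[b]) / (colsum_j + 0.8) / bg[b] )
```

Windows are scored on the *relative* scale
`(raw − min)/(max − min) ∈ [0, 1]`, where min/max are the sums of
columnwise extrema; the consensus scores exactly 1 and the anti-consensus
exactly 0 (same floating-point summation order, so the equality is exact,
not approximate). Windows containing an ambiguous base are skipped with a
notice.

`alleleImpact()` scans every window overlapping the variant base, on both
strands (by reverse-complementing the window), and classifies per
(motif, strand, offset) with presence threshold 0.80 and score-difference
threshold 0.05 on the relative scale:

* *created*: alt ≥ 0.80 > ref; *disrupted*: ref ≥ 0.80 > alt;
* *strengthened*/*weakened*: both present and |Δ| > 0.05.

Pairs that are absent in both alleles, or present in both with
|Δ| ≤ 0.05, are not reported: the output is exactly the set of motifs
present in only one allele or changing score by more than 5%, so a no-op
variant yields an empty call set. The 5% rule is applied at the *same*
(motif, strand, offset) in both alleles; shifted hits of the same motif
are treated as distinct windows. Only substitutions are supported
(multi-allelic records expand to one allele pair per alternate allele);
indels change the coordinate frame of every overlapping window and are
out of scope. Raising the presence threshold can only remove
created/disrupted calls, never add them — a monotonicity the property
tests exercise.

# The synthetic-data generator

`simulatePeaks()` emulates the one feature of real TF-binding tracks the
method depends on: *clustering*. Peak centers follow a hotspot mixture —
with probability `hotspotFraction` a peak falls normally (sd
`hotspotSd`) around one of `nHotspots` uniform hotspot centers, otherwise
uniformly — and lengths are normal, clipped to ≥ 1 bp. Normal (rather
than uniform-block) displacement makes within-cluster depth profiles
unimodal, so Gaussian trimming is exercised meaningfully. The defaults —
10 Mb over two chromosomes, 5,000 peaks of 300 ± 100 bp, 200 hotspots of
sd 500 bp, 70% hotspot-associated — are the package's standard validation
fixture: peak widths are ENCODE-like, and the hotspot load yields
clusters from singletons up to several tens of peaks, so thresholds
i = 2…40 are all populated.

`simulateSnps()` places each SNP inside the OTFR union with probability
`q`, uniformly within the chosen side. Placement conditions on the final
OTFR union, not on the hotspots, so the ground truth is exact by
construction: `E = q·G/L` (`expectedEnrichment()`), with `q = L/G` the
exact uniform null. What the simulator does *not* emulate: linkage
disequilibrium between SNPs, cell-line structure in the peak track,
sequence composition, and chromatin context. Passing the calibration and
recovery tests therefore shows the *statistic and its uncertainty* behave
as designed, not that real SNP samples are exchangeable — on real data,
LD-correlated SNPs make the effective sample smaller than `n_total`, and
the bootstrap SD is accordingly optimistic.

# Numerical and interface choices

* **Coordinates.** Internally everything lives in `GRanges` (1-based,
  closed), the native convention of the Bioconductor stack this package
  is built on. All 0-based half-open inputs (BED) and 1-based inputs
  (VCF, `chr:start-end` strings) are converted at the parsing boundary,
  and output columns named `pos0` are 0-based. The trim arithmetic is
  defined on 0-based base centers (`b + 0.5`) and floor/ceil produces a
  half-open interval, converted once to the internal convention.
* **Ordering and ties.** Clusters are numbered by (chromosome, start)
  with natural chromosome order; candidate SNPs rank by depth at the SNP,
  then cluster peak count, then id, making every output table
  deterministic. Motif consensus/anti-consensus ties resolve in A, C, G,
  T order.
* **Degenerate inputs.** Empty peak sets cluster to nothing; empty
  blacklists are the identity; `iMin < 2` is an argument error (an OTFR
  is by definition a region of *overlapping* loci); bootstrap of a
  size-1 sample against one region is exact (SD 0, collapsed CI).
* **Duplicates.** Duplicate peak records count separately — the method
  counts peaks, not distinct factors; `dedupeByFactor = TRUE` offers the
  stricter reading. Duplicate SNP ids warn but are kept.
* **BED output.** OTFR scores are peak counts clamped at 1000 (BED
  validity for genome browsers), with the true count in a 7th column that
  the reader prefers.

# Validation scale

The test suite validates against independent oracles at sizes chosen to
keep the whole suite in minutes on one CPU: per-base brute-force
equivalence on 200 random toy genomes (≤ 2,000 bp, ≤ 100 peaks) for
clustering, depth, trimming and annotation; nestedness over i = 2…40 on
the standard fixture; null calibration with 20,000 uniform SNPs across 20
seeds (B = 200); and four-fold recovery (`q = 4L/G`, n = 5,000, B = 500)
across 50 replicates with 99% CI coverage. `scripts/acceptance.R` reruns
the headline computations from a single seed.

# Limitations

* Cluster counts treat every peak record equally; cell-line replication
  in merged ENCODE-style tracks is preserved as given, not flattened
  (pass the track you consider canonical).
* The Gaussian trim is a two-moment approximation; multimodal clusters
  (two hotspots bridged by a long peak) are trimmed around their joint
  mean, which can keep the bridge and drop a mode's tail.
* No multiple-testing correction is applied across the `i` curve, and no
  LD pruning is done; both belong to the interpretation layer, not the
  statistic.
* JASPAR-style PWM calls over- and under-predict binding; motif-impact
  output is a screen for follow-up, not a verdict.
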