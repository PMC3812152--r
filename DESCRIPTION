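Package: otfr
Title: Regulatory SNP Prioritization via Overlapping Transcription
    Factor Binding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects putative regulatory SNPs by aggregating ChIP-seq
    transcription factor binding peaks into overlapping TF-binding
    regions (OTFRs), quantifying the enrichment of SNP sets inside
    OTFRs with bootstrap resampling, and scoring allele-specific
    creation or disruption of binding motifs from JASPAR-style
    position frequency matrices. Includes a synthetic-data simulator
    with known ground-truth enrichment so every pipeline stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: FunctionalGenomics, SNP, ChIPSeq, MotifAnnotation,
    GenomeAnnotation
RoxygenNote: 7.3.3
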