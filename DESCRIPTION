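Package: alleleMeth
Title: Allele-Specific DNA Methylation and Imprinting Analysis for Hybrid Embryos
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for allele-specific
    DNA-methylation and expression analysis of hybrid (two-parent) embryos:
    informative-SNP selection from parental variant calls with GATK-style hard
    filters, N-masking of the reference genome, SNP-based assignment of aligned
    bisulfite and RNA reads to the maternal or paternal allele, per-CpG
    methylation extraction with lambda spike-in conversion-efficiency
    estimation, differentially methylated region (DMR) calling and annotation,
    a negative-binomial differential-expression engine, an imprinted-gene
    filtration cascade with loss-of-imprinting calls, placenta calcification
    morphometry (Huang/Yen auto-thresholding, particle analysis, CCI/CCN), and
    gestational-outcome statistics (Kaplan-Meier curves, log-rank tests,
    abortion-time densities). A synthetic-data generator produces every input
    with known ground truth so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, DifferentialMethylation,
    Sequencing, Software
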