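Package: haplomix
Title: Direct Haplotype Inference from Aligned Long Reads by Classification
    Annealing EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A unified probabilistic framework that infers K consensus
    haplotypes directly from long sequencing reads aligned to a reference,
    without a separate variant-calling step. A two-stage generative model
    couples an evolution stage (reference to consensus haplotypes, with
    substitution, insertion and deletion mutations) with a sequencing stage
    (consensus to error-bearing reads, with mismatch errors and
    truncated-Poisson indel segment lengths). The model is fitted by a
    Classification Annealing EM algorithm; ploidy is chosen by five-fold
    cross-validated minimum error correction ratio (MECR). Includes the
    matching read simulator, correct phasing ratio (CPR) and MECR evaluation
    statistics, an SNV-calling byproduct, and SAM/BAM/FASTA/VCF bridges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
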