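Package: vectorsweep
Title: Insecticide-Resistance Genomics of Anopheles Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome studies of insecticide
    resistance in Anopheles mosquitoes. Summarises WHO tube-test bioassays
    with Abbott's correction and WHO resistance classification, applies
    GATK-style variant quality filters to phased VCFs, tabulates candidate
    and novel non-synonymous resistance SNPs by phenotype group with odds
    ratios, computes Rogers-Huff linkage disequilibrium, windowed Hudson
    FST between resistant and susceptible mosquitoes with a
    phenotype-permutation significance criterion, Garud's H12 genome-wide
    selection scan with haplotype subsampling, single-linkage haplotype
    clustering in windows of interest, and a soft-clipped-read screen for
    known copy-number-variant alleles. Includes a synthetic-data generator
    that produces phenotyped genotype panels, VCF/SAM fixtures and bioassay
    counts with known ground truth, so every stage is testable without
    access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    rtracklayer,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
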