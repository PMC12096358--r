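Package: exocohort
Title: Exome Cohort Variant Prioritization Against Population Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritizing damaging variants whose allele
    frequencies differ between a sequenced patient cohort and a large reference
    population. Starting from a multi-sample VCF, per-allele damage labels
    (TOLERATED/DELETERIOUS), and a population allele-frequency VCF, it selects
    loci carrying homozygous damaging genotypes, compares cohort allele counts
    with the population expectation by an exact two-sided Poisson rate test,
    applies a recurrence rule to loci absent from the reference, collapses
    surviving loci to genes, tests gene-category enrichment with Fisher's exact
    test and Benjamini-Hochberg FDR control, and associates genotypes with
    quantitative phenotypes under a dominant model. A seeded synthetic-cohort
    generator produces Hardy-Weinberg genotypes with planted signal so that
    every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
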