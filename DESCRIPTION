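Package: hweCNV
Title: Copy Number Variant Frequency Estimation from SNP Array Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates population frequencies of common copy-loss (null
    allele, loss of heterozygosity) and copy-gain variants from biallelic
    SNP array genotype calls. Combines closed-form trinomial
    Hardy-Weinberg estimators of deletion- and duplication-allele
    frequencies with signal-intensity evidence parsed from per-sample CNV
    call lists (PennCNV rawcnv format), calibrates mean-plus-one-SD
    selection thresholds, merges selected markers into CNV regions, and
    confirms regions against documented CNV catalogs. Includes exact
    Poisson confidence intervals for deletion-allele frequencies derived
    from homozygote counts, diagnostics for misplaced sex-chromosome
    markers, and a seeded simulator of genotype panels with planted CNV
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SNP, GenomeWideAssociation, Genetics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
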