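Package: maecall
Title: Classification of Monoallelic and Biallelic Expression from Matched
    RNA-Seq and Exome SNV Calls
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies every annotated gene, isoform and exon in each sample
    of a cancer cell-line cohort as monoallelically or biallelically expressed
    (or copy-number loss, no-SNV-data, not-expressed, unresolved) from matched
    RNA-seq and whole-exome heterozygous SNV calls, exon-level read counts and
    gene-level copy number. Includes downstream statistics: per-gene summary
    tables with percent-monoallelic, imprinted-versus-background comparisons
    with stratified subsampling, a tissue-specificity chi-square test on
    isoform patterns, an exact two-sided binomial "flip test" for base-biased
    monoallelic expression, and isoform-group drug-response association with
    Benjamini-Hochberg FDR control. A seeded synthetic-cohort generator emits
    complete input bundles (GTF, VCF, count tables, copy number, drug
    response) with known truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
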