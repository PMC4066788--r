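Package: imprintseq
Title: Parent-of-Origin Expression and Allele-Specific Methylation in
    Reciprocal-Cross Endosperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic imprinting (maternally and paternally expressed
    genes) in triploid endosperm from reciprocal-cross RNA-seq by counting
    parental-allele reads at diagnostic SNPs and testing each locus against
    the 2 maternal : 1 paternal genomic dosage with exact one-sided binomial
    tests, joint reciprocal P-values (second-order statistic), and rank-based
    false-discovery rates. Also calls CpG methylation from bisulfite reads,
    segments differentially methylated regions between endosperm and embryo,
    identifies allele-specific methylation at imprinted genes, and tests
    association of imprinting with transposable-element proximity, genomic
    clustering, and endosperm hypomethylation. Includes a fully seeded
    synthetic-data generator (parental haplotypes, reciprocal endosperm
    transcriptomes with known imprinting truth, bisulfite reads) so the whole
    pipeline can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
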