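Package: salsnp
Title: Candidate-Gene SNP Association Analysis for Low-Salinity Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene SNP association studies of binary
    stress-tolerance phenotypes in aquaculture species. Implements
    chromatogram peak-ratio genotype calling, minor-allele-frequency
    filtering, per-locus case-control statistics (odds ratios with Woolf
    confidence intervals, chi-square and Fisher exact tests, single-locus
    logistic effect sizes), per-group genetic diversity summaries (observed
    and expected heterozygosity, effective allele number, polymorphic
    information content), expectation-maximization haplotype frequency
    estimation from unphased genotypes with case-control haplotype
    association tables, a genotype-frequency-product multi-locus classifier
    with validation accuracy, correlation-matrix PCA for growth grouping,
    relative expression analysis by the 2^-ddCt method, and a seeded
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
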