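Package: lohassoc
Title: Candidate-SNP Case-Control Association and Paired Tumor-Normal
    Loss-of-Heterozygosity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for replication studies of candidate cancer-susceptibility
    single-nucleotide polymorphisms (SNPs) and for genotype-based somatic
    allelic-imbalance analysis in paired tumor and adjacent-normal tissue.
    Implements per-SNP allelic and genotypic chi-square tests,
    Hardy-Weinberg goodness-of-fit tests, risk-oriented allelic odds ratios
    with Wald confidence intervals, Bonferroni and Westfall-Young max-T
    permutation adjustment, two-proportion power calculations, genotype
    principal-component stratification diagnostics with the genomic
    inflation factor, and loss-of-heterozygosity (LOH) calling from paired
    hard genotype calls with allele-specific retention tests. A synthetic
    cohort generator produces case/control and paired tumor genotype panels
    under Hardy-Weinberg equilibrium, per-allele odds models, linkage
    disequilibrium constraints, and a purity-dependent LOH miscall model,
    so the whole pipeline is testable without access to restricted
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
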