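Package: triohrr
Title: Family-Based Candidate-Gene Association with Trio Pseudo-Controls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for candidate-gene case-control association studies that
    augment unrelated controls with pseudo-controls built from affected-child
    trios under the Haplotype-Relative-Risk principle.  Covers PLINK text
    PED/MAP input and output, SNP quality control (minor-allele frequency,
    missingness, exact Hardy-Weinberg test, trio Mendel-error rate), allelic
    and genotypic chi-squared association with odds ratios, max-T permutation
    correction for multiple testing, EM-based two-locus linkage-disequilibrium
    estimation with greedy tag-SNP binning, GATES gene-level p-value
    combination, analytic power for the allelic test, and a synthetic-cohort
    simulator with block LD structure and a log-additive disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
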