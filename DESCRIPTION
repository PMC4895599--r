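Package: exomecontrast
Title: Case-Control Exome Variant Prioritization with a Filter-Cascade Audit Trail
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges per-sample germline variant calls into a cohort genotype
    matrix and applies group-discordance, consequence, deleteriousness,
    novelty and zygosity-contrast filters to nominate candidate prognostic
    marker variants in small case-control exome cohorts, recording a full
    filter-cascade audit trail.  Includes read-support quality control,
    paired diagnosis/remission constitutive-genotype checks, orthogonal
    (Sanger-style) genotype concordance, Hardy-Weinberg chance-discordance
    statistics for the perfect-segregation filter, and a synthetic cohort
    generator with planted markers and a truth table so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
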