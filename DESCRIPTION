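Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating per-SNP association tables, allele
    harmonization with palindrome handling, instrument selection (genome-wide
    significance filtering, greedy LD pruning, confounder-trait exclusion,
    proxy substitution, F-statistics), a suite of causal estimators
    (fixed- and random-effect inverse-variance weighting, maximum likelihood,
    simple and weighted median and mode, MR-Egger regression with its
    pleiotropy intercept test), leave-one-out / forest / funnel sensitivity
    diagnostics, statistical power for binary outcomes, and a generator of
    synthetic two-sample summary statistics with known ground truth. Ships a
    nine-SNP homocysteine / atrial-fibrillation instrument table as a worked
    fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
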