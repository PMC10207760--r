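Package: mrpipe
Title: Two-Sample and Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and drug-target
    MR from GWAS summary statistics: instrument selection (genome-wide
    significance filtering, greedy LD clumping, confounder screening,
    F-statistic filtering), allele harmonization with palindromic-SNP
    handling, causal estimation (inverse-variance weighted, MR-Egger,
    weighted median, simple and weighted mode, Wald ratio), sensitivity
    diagnostics (Cochran's Q, Egger intercept test, MR-PRESSO global,
    outlier and distortion tests), multivariable MR, and a synthetic
    two-sample GWAS summary-statistics generator with known ground truth so
    every stage of the workflow is testable without cohort data. Includes
    end-to-end drivers mirroring a blood-pressure and antihypertensive
    drug-class analysis of a disease-onset outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
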