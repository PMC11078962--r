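Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of Metabolite GWAS
    Against Disease Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of
    many exposures (for example, serum metabolites) against a binary disease
    outcome using GWAS summary statistics.  Covers instrument selection
    (significance filtering, LD clumping, per-SNP F statistics, exclusion of
    outcome-associated variants), allele harmonization with palindromic-SNP
    handling, five causal-effect estimators (multiplicative random-effects
    IVW, MR-Egger, weighted median, simple and weighted mode), heterogeneity
    and pleiotropy diagnostics (Cochran's Q, Egger intercept, Radial MR,
    MR-PRESSO, leave-one-out), LD score regression for SNP heritability and
    genetic correlation with block-jackknife standard errors, bidirectional
    (reverse) MR, and a three-criterion causal decision rule.  A synthetic
    summary-statistics generator with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
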