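Package: triangulateMR
Title: Evidence Triangulation for Causal Inference from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Triangulates three lines of genetic evidence for a causal
    relationship between two traits from GWAS summary statistics: bivariate
    LD-score regression for genetic correlation, two-sample Mendelian
    randomization with a full pleiotropy-robust sensitivity suite (IVW,
    MR-Egger, weighted and penalized weighted median, MR-PRESSO, MR-RAPS,
    Steiger directionality, multivariable MR), and Bayesian colocalization
    via per-variant approximate Bayes factors with per-instrument region
    windows. A decision table maps the three tracks' outcomes onto ten
    evidence patterns and nine causal-evidence explanations. Includes
    seeded generators for LD panels and summary statistics under causal,
    pleiotropic, confounded and colocalization scenarios so the whole
    pipeline is testable without external data, plus closed-form power
    calculations for binary-outcome MR.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
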