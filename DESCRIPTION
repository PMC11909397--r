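Package: strokemr
Title: Two-Sample Mendelian Randomization for Clonal Hematopoiesis and Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A complete two-sample Mendelian randomization inference chain for
    linking clonal-hematopoiesis driver mutations to stroke subtypes from GWAS
    summary statistics: effect-size/standard-error reconstruction from odds
    ratios and P values, P-value instrument selection with greedy LD clumping,
    four-rule allele harmonization with a per-SNP disposition log,
    random-effects inverse-variance-weighted estimation with Cochran's Q and
    MR-Egger sensitivity tests, two-step product-method mediation with
    proportion mediated, and Bayesian colocalization via Wakefield approximate
    Bayes factors.  A bundled synthetic GWAS generator with known ground truth
    makes every stage testable without external downloads, and a grid driver
    runs the full exposure-by-outcome analysis matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
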