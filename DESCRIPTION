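Package: centermod
Title: Centering-Aware Moderated and Polynomial Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary least-squares tools for moderated (product-term) and
    polynomial regression that make centering semantics explicit and correct.
    Builds design matrices with full provenance of centering and
    standardization (products and powers are always recomputed after
    transforming their components), estimates conditional (simple) slopes at
    arbitrary moderator values via the delta method, assesses main effects
    through hierarchical delta-R-squared tests, computes order-of-operations
    correct standardized coefficients together with semipartial correlations
    and variance inflation factors, and provides a formal audit certifying
    which quantities are invariant to the choice of centering constants and
    which are merely reparameterized. Includes deterministic generators for
    interaction and quadratic fixtures with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
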