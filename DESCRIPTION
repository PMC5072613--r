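Package: ithIHC
Title: Intratumoral Heterogeneity Analysis of Immunohistochemistry Loss Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intratumoral heterogeneity (ITH) from focus-level
    immunohistochemistry (IHC) scores on tissue microarrays, as applied to
    chromatin-regulator losses (PBRM1, ARID1A, SETD2, BRG1, BRM) in clear cell
    renal cell carcinoma. Converts staining fractions to ordinal scores, calls
    focus- and tumor-level expression losses, reconstructs per-tumor clonal
    trees by clonal ordering of loss support sets (laminar-family
    construction), classifies events as truncal or branch and trees by shape,
    tests all marker pairs for co-loss with an exact two-sided Fisher test,
    and simulates cohorts with planted clone trees for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
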