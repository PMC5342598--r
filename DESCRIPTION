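Package: ncrprofile
Title: Splice-Variant Profiling of the Natural Cytotoxicity Receptors NKp44 and NKp30
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies NKp44 (NCR2) and NKp30 (NCR3) splice-variant fractions
    from qPCR cycle-threshold tables (2^-dCt relative expression) and from
    TCGA-style normalized RSEM gene/isoform tables, calls mRNA positivity,
    classifies inhibitory versus activating receptor profiles by threshold
    rules (NKp44-1 dominance at 66 percent; NKp30a versus NKp30c), types
    profile shifts between matched tumor and normal samples, and computes
    cohort statistics: incidence tables, profile distributions, a two-sided
    Fisher exact test computed by hypergeometric enumeration, and two-tailed
    paired t-tests. Includes a synthetic-cohort generator (Dirichlet isoform
    mixtures, positivity dropout, valid TCGA barcodes with matched
    tumor/normal pairs) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
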