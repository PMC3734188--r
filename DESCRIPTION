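Package: scwdiff
Title: Spectral-Count-Weight Differential Expression for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free differential protein expression from MS/MS spectral
    counts, built around the spectral count weight (SCW): a protein's spectral
    count divided by the total spectral count of its MS analysis. Reads
    ProteinProphet-style per-run identification tables, applies an
    identification-probability filter, assembles a zero-filled count matrix
    over the union protein set, normalizes to SCW, tests each protein with a
    pooled two-sample Student's t-test across technical replicates, and
    selects differential proteins with a three-criteria cascade (distinct
    peptide support, presence in every run of the elevated group, fold change
    threshold). Selected proteins are partitioned into secreted versus
    non-secretory classes from dual-algorithm signal-peptide prediction flags.
    Includes a negative-binomial spectral-count simulator with spike-in fold
    changes and abundance-dependent detection dropout for benchmarking
    sensitivity and false discovery of the cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
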