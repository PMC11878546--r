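Package: mitocall
Title: Statistical Calling of Lineage-Informative Mitochondrial Mutations in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls mitochondrial DNA mutations in single cells from per-base
    allele count matrices (mgatk-style per-base tables or cellSNP-lite-style
    sparse AD/DP matrices). For each locus the wild-type allele is defined
    reference-free as the base with the highest median count across cells; a
    two-component binomial mixture fitted by EM preselects likely wild-type
    reference cells; a beta-binomial null model fitted on those cells by
    maximum likelihood yields a per-cell lower-tail probability, adjusted per
    locus by the Benjamini-Hochberg procedure into a mutation q-value.
    Includes mutation-set filtering, precision metrics against cell labels,
    cell-type clustering on mutation frequencies, staircase heatmap ordering,
    a synthetic data generator matching the model's assumptions, and a
    directory-backed hierarchical store for raw and intermediate results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
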