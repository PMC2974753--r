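Package: hdeqtl
Title: Hellinger-Distance Prioritization of Expression Traits in eQTL Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prioritizes expression traits in expression quantitative trait
    locus (eQTL) studies by how closely the genome-wide corrected p-value
    profile of each trait matches a reference distribution modelling a single
    exceptional association. Implements single-marker LOD mapping for haploid
    biparental crosses, permutation-based genome-wide significance, the
    per-trait Hellinger distance statistic between binned p-value profiles and
    a cubic reference distribution, trans-eQTL hotspot detection against a
    simulated null, cis/trans classification, and a synthetic-data generator
    for haploid crosses with planted genetic architectures.
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
    optparse,
    jsonlite
Config/testthat/edition: 3
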