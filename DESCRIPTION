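Package: halosucc
Title: Community Phylogenetics and Plot Ecology of Plant Succession on
    Saline Coasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing plant community succession on newly
    emerged saline coastal land. Grafts species missing from a dated
    backbone phylogeny as basal polytomies within their genera or
    families, computes patristic distances, mean pairwise distance (MPD)
    with permutation null distributions for phylogenetic clustering of
    lost and acquired species, and a rank-step taxonomic distinctness
    index. Provides exact hypergeometric enrichment tests for family-level
    species loss and gain and for order overrepresentation, plus plot-level
    occupancy statistics: stratified Fisher tests of microtopography
    preference with Bonferroni correction, Mann-Whitney comparisons of
    bare ground and salinity, a Spearman screen of bare ground against
    electrical conductivity by soil depth, trait enrichment, nurse-plant
    association and an extinction-randomness prevalence test. A
    deterministic synthetic-data generator emulates the survey design so
    every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
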