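Package: clonalscape
Title: Clonal and Spatial Population Genetics for Partially Clonal Plants in
    Riverscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for codominant microsatellite surveys of
    partially clonal aquatic plants sampled along rivers. Discriminates clones
    from multilocus genotypes (MLG/MLL collapse with psex), quantifies
    genotypic diversity (richness, effective numbers, Pareto beta,
    rarefaction), pairwise relatedness (Wang's moment estimator with
    permutation tests), per-site allelic and heterozygosity statistics with
    bootstrap confidence intervals and clone correction, among-site
    differentiation (Weir-Cockerham theta, Hedrick's G''ST, Jost's D),
    water-constrained least-cost distances on a conductance raster,
    isolation-by-distance Mantel tests, correspondence analysis, and
    permutation contrasts between tidal regimes. Includes a synthetic-data
    generator emulating the sampling design of a river-spanning clonal plant
    survey so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
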