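Package: jaykin
Title: Deconstructing Fine-Scale Isolation-by-Distance with Pedigrees,
    Dispersal Curves and Spatial Coalescent Simulation
Version: 0.1.0
Authors@R:
    person("Archbold", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting fine-scale isolation-by-distance in
    continuously monitored pedigreed populations. Provides genomic
    identity-by-descent estimators for autosomal and Z-linked SNPs
    (including hemizygous females), recursive pedigree kinship for
    autosomal and ZW inheritance, decay-of-relatedness statistics (loess
    half-decay distance delta with BCa bootstrap intervals, Mantel
    correlograms, quantile-binned means, PC-versus-northing
    correlations), forward dispersal simulations of distances between
    relatives, and a pedigree-parameterized spatial coalescent (model
    ladder M0-M4) predicting identity-by-descent as a function of
    geographic distance. A spatially explicit synthetic-population
    generator with sex-specific leptokurtic dispersal, immigration and
    gene-dropped genotypes makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
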