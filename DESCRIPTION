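Package: isonymica
Title: Surname-Based Urban Population Structure from Isonymy and Affinity Networks
Version: 0.1.0
Authors@R: person("Registry", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses two surname networks that summarise the
    population structure of a city from a person-level registry carrying
    paternal and maternal surnames, planar coordinates, and block-level
    income. The first network links surname pairs whose co-occurrence
    exceeds a random-pairing expectation (an affinity network); the second
    links grid cells of the city by isonymic distance (Lasker, Nei, or
    Euclidean chord), pruned to a sparse skeleton by iterated edge-disjoint
    minimum spanning trees with a structural-dissimilarity (D-value)
    stopping diagnostic. Both networks are clustered with consensus
    modularity optimisation and profiled by socioeconomic status, surname
    diversity (effective surname number), and historical-cohort
    representation. A synthetic-city generator with planted group structure
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
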