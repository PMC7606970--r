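Package: haloscape
Title: Spatial-Scale Analysis of Halite Endolith Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the spatial heterogeneity of endolithic
    microbial communities in desert halite nodules, from regional
    (kilometre) down to intra-nodule (centimetre) scales. Includes
    detection of dew and fog events from relative-humidity logger series,
    estimation of photosynthetically active radiation inside nodules from
    transmission spectra, cell-density estimation from epifluorescence
    field counts, first-principles alpha and beta diversity (Bray-Curtis,
    weighted UniFrac, Faith phylogenetic diversity, principal coordinates),
    permutation and compositional tests (PERMANOVA, ANCOM W), slice
    standardisation of relative abundances, vertical-gradient tests, and
    distance-scale decay of community similarity. A synthetic-data module
    generates nested study designs with humidity- and light-dependent taxa
    and community drift for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
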