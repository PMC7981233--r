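Package: anolespat
Title: Spatial Distribution, Kinship and Parentage of Territorial Lizard
    Populations from Mark-Recapture Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing what drives the spatial distribution of
    territorial lizards (green anole size morphs) in a fenced urban park:
    home-range polygons and areas from seasonal mark-recapture captures
    coarsened to bush habitats, average-distance spatial statistics for
    heavyweight and lightweight males, microsatellite genotype quality
    control (Hardy-Weinberg and linkage-disequilibrium tests with
    Holm-Bonferroni correction), Loiselle pairwise kinship with distance-class
    autocorrelograms and Mantel isolation-by-distance tests, a
    genotyping-error-aware likelihood parentage engine run under a sequential
    cohort-stacking, triplicate-consensus procedure, pedigree inbreeding
    coefficients, and parent-offspring home-range inheritance tests. Includes
    an individual-based simulator of a fenced park population (polygynous
    mating, Mendelian microsatellite inheritance, male-biased dispersal,
    seasonal sampling) that emits capture, genotype and habitat files plus a
    ground-truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
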