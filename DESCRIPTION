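Package: glycanyon
Title: Glycan Fragment Mapping of Glycosidase Binding Canyons
Version: 0.1.0
Authors@R:
    person("Glycanyon", "Developers", email = "glycanyon@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing protein-carbohydrate complexes of glycoside
    hydrolases with elongated glycan-binding grooves ("canyons"). Parses PDB
    coordinate files, detects pyranose rings and glycosidic linkages, assigns
    anomeric configuration, computes Cremer-Pople ring puckering parameters
    with canonical conformer classification, performs Kabsch superposition
    with sequence-guided iterative outlier rejection, merges sugar fragments
    from soaked complexes into a consensus subsite map with glycosidase
    subsite nomenclature, reassembles composite glycans and classifies their
    shape, and runs desk-scale family analyses: sequence similarity networks,
    ortholog co-distribution statistics, and conservation profiling mapped
    onto structures. Includes seeded synthetic data generators for sugars,
    glycans, planted complexes, sequence families, and alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
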