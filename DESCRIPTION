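Package: netage
Title: Evolutionary Age Analysis of Gene Networks from Phylogenetic Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to trace when the genes of a cellular network emerged in
    evolution and whether its regulatory interactions are age-coupled.
    Builds gene-by-species presence/absence matrices (phylogenetic profiles)
    from pairwise ortholog hit tables, assigns gene ages on an ordered scale
    of phylostrata by the oldest-hit rule and by Dollo and Wagner gain-loss
    parsimony on a species tree, computes emergence curves and age-enrichment
    statistics (Fisher exact, Mann-Whitney U, Bonferroni), detects gene losses
    in model organisms, and tests age assortativity of posttranslational
    modification target-modifier networks against free and stratified
    permutation null models. Includes simulators for single-gain/loss gene
    histories along a tree and for age-coupled modification networks, and a
    packaged transcription of a curated DNA-damage-response modification
    pair table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
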