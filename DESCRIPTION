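Package: synwaves
Title: Developmental Synaptome Mapping Statistics and Synaptic Response Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental synaptome mapping studies:
    synthetic cohort generation with known ground-truth effect sizes, synaptic
    puncta classification into molecular types and morphological subtypes,
    Bayesian Monte-Carlo estimation of Cohen's d with Benjamini-Hochberg
    correction across brain subregions, Shannon synapse-diversity maps,
    subregion similarity matrices with similarity-ratio and small-world
    network statistics, and a short-term-plasticity simulator of CA1 stratum
    radiatum synaptic responses with depression, dual facilitation and
    spatial scaling by PSD95/SAP102 intensity gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
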