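Package: phycomacro
Title: Hierarchical Bayesian Meta-Analysis of Microalgal Macromolecular Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for curating literature-compiled measurements of the
    macromolecular composition of microalgae (protein, lipid, carbohydrate,
    ash, RNA, DNA and chlorophyll-a as percent dry weight or mass per cell)
    and estimating phylum-level and pan-microalgal median composition with a
    three-level hierarchical Bayesian model (observations within species
    within phyla), fitted by an in-package Gibbs sampler with slice-sampling
    updates for the variance components. Includes the nitrogen-to-protein
    conversion correction for eukaryotes, within-study macromolecular mass
    ratios modelled on the log scale, highest-density credible intervals,
    inverse-variance-weighted grand means, pairwise phylum contrasts,
    variance decomposition across taxonomic levels, stoichiometric prediction
    of molar C:N from macromolecular profiles, and a synthetic-data generator
    with ground truth for parameter-recovery and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
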