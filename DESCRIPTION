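Package: xfba
Title: Community Flux Balance Analysis with Fixed Abundances and Unequal Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for two-member
    microbial communities in which member abundances are fixed but member
    growth rates differ, as in free-living diazotrophs that maintain a
    sub-population of non-growing nitrogen-fixing cells alongside growing
    cells. Provides reading and writing of genome-scale metabolic models in
    tabular (TSV/XLSX) and JSON form, stoichiometric-matrix assembly, dead-end
    detection, biomass-reaction construction from macromolecular composition,
    flux balance analysis with parsimonious reporting, flux variability
    analysis, community-model construction with a shared metabolite pool,
    abundance-scaled stoichiometry with growth-ratio and storage-polymer
    coupling constraints (the XFBA formulation), scenario batteries
    (carbon/nitrogen source screens, inter-member exchange robustness,
    abundance sensitivity, oxygen/terminal-oxidase scans), and principal
    component analysis of flux distributions. Includes an analytically
    tractable toy-cell generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
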