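Package: phstab
Title: pH-Dependent Electrostatic Contribution to Protein Folded-State Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the pH-dependent electrostatic contribution to protein
    folded-state stability from structure, using Debye-Hueckel screened
    Coulomb interactions between ionisable groups and either exact
    enumeration or Metropolis Monte Carlo sampling of protonation
    microstates. Includes motif-based extraction of immunoglobulin (IgG)
    domains from sequences and structures, charge-composition statistics,
    rule-based charge-neutralising mutation scans, detection of salt bridges
    and carboxylate hydrogen-bond networks, pH x ionic-strength stability
    heat maps, and a synthetic-structure generator so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
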