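Package: mdfpath
Title: Thermodynamic and Enzyme-Constrained Metabolic Pathway Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-constraint analysis of metabolic networks combining
    stoichiometric mass balance, a total proteome budget on enzyme cost
    (flux over catalytic efficiency kcat/MW), and thermodynamic driving
    forces derived from standard transformed reaction Gibbs energies and
    bounded metabolite concentrations. Implements max-min driving force
    (MDF) optimization as a mixed-integer linear program, the MDF versus
    required-yield staircase with stage detection, identification and
    classification of thermodynamic bottleneck reactions, limiting
    metabolites and key enzymes, and structural model correction by
    merging partial reactions catalyzed within a single enzyme structure
    (multifunctional enzymes, complexes and substrate channels) into
    overall reactions. Reads BiGG-style JSON models with tabular
    thermodynamic and kinetic parameters, and ships seeded generators of
    small networks with designed thermodynamic bottlenecks and coupled
    enzyme motifs for testing every analysis stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
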