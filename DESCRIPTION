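Package: rldesign
Title: Evolutionary QSPR Design of Rhamnolipid Biosurfactants
Version: 0.1.0
Authors@R:
    person("rldesign", "maintainers", email = "rldesign@example.org",
           role = c("aut", "cre"))
Description: Tools for designing rhamnolipid biosurfactants from harmonized
    literature and laboratory data. Provides tabular databases of biosynthesis
    and micellar-solubilization experiments, literature harmonization rules
    (weighted congener descriptors, mono/di composition resolution, C:N
    ratios), chained-equations imputation of missing descriptor cells, a gene
    expression programming (GEP) symbolic-regression engine with the repeated
    80:20 split fitting protocol, permutation importance and derivative-sign
    contribution analysis, per-descriptor applicability domains, reduction of
    surface-tension isotherms to critical micelle concentrations (CMC) and of
    solubility curves to molar solubilization ratios (MSR), a synthetic-data
    generator for end-to-end testing, and forward/inverse calculators for
    task-specific biosurfactant design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
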