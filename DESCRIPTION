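Package: petristruct
Title: Structural Analysis and Continuous Simulation of Biochemically
    Interpreted Petri Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents biochemical reaction networks as place/transition
    Petri nets and analyses their structure without constructing a state
    space: exact enumeration of minimal semi-positive P- and T-invariants
    by integer Fourier-Motzkin (Farkas) elimination, coverage predicates
    (CPI/CTI/SCTI), structural-deadlock fixpoints, reduction of a network
    to its steady-state core, abstract dependent transition (ADT) sets with
    hierarchical coarsening into macro transitions, and pathway
    enumeration. The same nets are interpreted as mass-action ordinary
    differential equation systems for steady-state, dose-response and
    knock-out experiments. Ships a fully worked case study: the
    hypoxia-response (HIF) switch network, its invariant tables, core
    reduction, coarse structure and oxygen titration experiments. Reads
    and writes a plain-text reaction list format, PNML and SBML (import).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
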