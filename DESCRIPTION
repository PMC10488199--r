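Package: pumplipid
Title: Lipid Regulation Analysis for Membrane Proton Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how anionic phospholipids
    stimulate plasma-membrane H+-ATPases. Converts ACMA fluorescence
    quench traces from proteoliposome assays into initial proton-pumping
    rates and fold changes, fits Boltzmann sigmoids to detergent
    solubilization series, analyses coarse-grained bilayer trajectories
    for residue-lipid contacts, leaflet-resolved lipid density and
    enrichment maps, 3D density grids and lipid interaction sites, scores
    alignment-column conservation of contact residues across P-type
    ATPases, and summarises per-condition rates with one-way ANOVA,
    Tukey HSD and compact letter displays. A synthetic-data module
    generates traces, titration series and bilayer trajectories with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
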