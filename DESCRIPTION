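Package: adsim
Title: Network Model of Amyloid-Beta and Tau Protein Dynamics in
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the progression of Alzheimer's disease on brain
    connectomes represented as two superposed weighted graphs: a proximity
    graph on which extracellular amyloid-beta diffuses, and a connectivity
    graph on which intraneuronal misfolded tau spreads.  Both proteins
    follow five-compartment Smoluchowski coagulation-diffusion systems
    (monomers, dimers, short proto-oligomers, long oligomers, and inert
    plaques or tangles), coupled to a conservative transport equation for
    the probability density of neuronal malfunction on each parcel.
    Includes readers for edge-list and GraphML connectomes, a synthetic
    connectome generator with designated entorhinal seed regions, scenario
    presets exploring the amyloid cascade hypothesis and amyloid-tau
    synergy, and exporters for global and regional burden and damage time
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
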