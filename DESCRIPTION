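Package: vagusnet
Title: Connectome and Peristalsis Analytics for the Insect Vagus Nerve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative circuit analysis for electron-microscopy
    reconstructions of the enteric/vagus nervous system of the Drosophila
    larva and for the accompanying foregut peristalsis physiology.
    Provides SWC skeleton handling with geodesic geometry and dendrogram
    linearization, polyadic connector bookkeeping (synapse count and
    input-fraction matrices, cluster budgets, hemisphere budgets,
    peripheral active-zone tallies), direct and interneuron-mediated
    sensory pathway weights with modality rollups, bilateral asymmetry
    indices with rank-correlation symmetry testing, geodesic
    synapse-placement analysis, two-ROI fluorescence trace analytics
    (event detection, trigger/wave pairing, cycle frequency, completion
    rate, per-animal ratio statistics), and seeded synthetic generators
    for bilateral clustered connectomes and calcium traces with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    igraph,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
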