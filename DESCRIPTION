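Package: benchpose
Title: Self-Docking Benchmark Evaluation, Ranking and Screening Utilities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates ensembles of docking poses against crystallographic
    reference ligands for self-docking benchmark studies: heavy-atom RMSD
    without refitting, per structure-protocol RMSD statistics (minimum,
    maximum, average), the N(RMSD<R) count and a 0-3 Protocol Score,
    protocol and protein rank aggregation, and colour-map reporting.
    Also provides binding-cavity geometry from mass-weighted ligand
    centroids, a discrete-event simulation of license-constrained job
    dispatch lanes, virtual-screening library splitting, merging and
    global ranking, and a synthetic pose generator that produces pose
    sets with exactly prescribed RMSDs for engine-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
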