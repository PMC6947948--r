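Package: TripletNet
Title: Dysregulated Cross-Role Triplet Analysis on Protein Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enumerates immune-, inflammation- and disease-role gene triplets
    (triangles) on a protein-protein interaction network, scores their
    dysregulation between case and control expression profiles with a
    two-part score (differential-expression p-value product and correlation
    rewiring) combined by equally weighted ranks, assigns empirical
    significance by sample-label permutation, extracts core clusters from the
    dysregulated subnetwork by greedy cohesiveness optimisation, classifies
    samples by subsampled k-means consensus clustering with CDF/delta-area
    model selection, and overlays drug-target interactions to rank drug
    repurposing candidates. Includes a synthetic-data generator with planted
    dysregulated triplets for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    MASS,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TripletNet-package.R'
    'catalog.R'
    'triplet-network.R'
    'scoring.R'
    'clustering.R'
    'consensus.R'
    'data-io.R'
    'drug-overlay.R'
    'simulate.R'
    'pipeline.R'
    'utils.R'
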