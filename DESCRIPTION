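Package: mvcpm
Title: Multiview Clustering of Multi-Omics Data with a Penalty Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative clustering of samples measured on several omics
    layers (views). Each layer is converted into a patient-patient k-nearest
    neighbour similarity network; the per-view graph Laplacians are coupled
    into a block operator and the resulting multiview spectral clustering
    problem, with one orthogonality constraint per view, is solved with a
    first-order penalty method using alternating Barzilai-Borwein stepsizes.
    Includes a stochastic block model simulator for benchmarking, Rand index
    and silhouette evaluation, log-rank survival comparison of clusters, and
    command-line entry points for the simulation and real-data pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
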