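Package: swarmSpectra
Title: Spectral Analysis of Spatiotemporal Gene Expression in Expanding
    Bacterial Swarms
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing spatiotemporal transcriptome, phenotype and
    metabolite measurements from exponentially expanding bacterial swarm
    colonies. Fits a shared exponential boundary across replicates and
    non-dimensionalises sample coordinates onto a common space-time domain,
    builds a domain-specific orthonormal polynomial basis by Gram-Schmidt
    orthogonalisation under an exponentially weighted inner product,
    represents each gene's expression field by its spectral coefficients, and
    scores, selects and clusters genes by the strength and shape of their
    spatiotemporal pattern. Also provides count filtering and trimmed mean of
    M-values (TMM) normalisation, kymograph heat-map assembly,
    microscopy-derived collective-motion phenotype metrics (nematic order,
    rafting, non-motile clusters, density fluctuations), extracellular
    metabolite time-series analysis (depletion and secrete-then-consume
    timing against a diffusion timescale), and a synthetic-data generator
    emulating the full study design for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
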