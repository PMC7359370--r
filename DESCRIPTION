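Package: caensemble
Title: Correlated Ensemble Analysis for In Vivo Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for one-photon calcium-imaging studies of
    neuronal ensembles during contextual fear conditioning. Detects Ca2+
    transient events from extracted fluorescence traces (z-scaling against a
    silent-timepoint baseline, amplitude and minimum-duration thresholds,
    multi-peak splitting), builds Pearson correlation graphs over 1-s
    binarized event rasters, computes per-neuron graph metrics (correlated
    pair ratio, clustering coefficient, component membership), classifies
    stimulus-responsive cells against shuffle nulls, partitions shock-partner
    ensembles with a resampling bias control, and relates cross-session
    changes in correlated activity to freezing behavior by linear regression.
    Includes a ground-truthed synthetic-data generator (Poisson background
    events, latent-source correlated modules, GCaMP-like kernels) so every
    stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
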