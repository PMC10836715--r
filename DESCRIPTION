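Package: neuroarrow
Title: Irreversibility and Nonequilibrium Dynamics of Multichannel Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the arrow of time in multichannel
    electrophysiological recordings (ECoG/LFP-like signals). Implements
    windowed pairwise signal irreversibility from time-shifted forward and
    time-reversed Pearson correlations, its decomposition across cortical
    systems and 1-Hz frequency bins, spectrogram-based behavioral-stage
    classification (PCA + k-means), Gaussian-emission hidden Markov network
    states with switching-rate, fractional-occupancy, lifetime, entropy
    production, determinism, degeneracy and mutual-information summaries,
    and an autoencoder latent-space analysis in which binarized latent
    coordinates yield pairwise entropy-production features for balanced
    random-forest stage classification. A synthetic-recording generator with
    planted coupling asymmetry, spectral stage signatures and Markov network
    states makes every stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
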