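Package: fcnet
Title: Task-Related Functional Network Inference with Bootstrap Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers task-related functional connectivity networks from
    multichannel brain-voltage recordings (EEG/ECoG) with principled
    uncertainty. Coupling between sensors is measured by the trial-pooled
    absolute correlation, and coupling between regions of interest by the
    first canonical correlation of the channel groups. Observed statistics
    are compared to per-edge null distributions bootstrapped from baseline
    (task-free) intervals, thresholded with Benjamini-Hochberg false
    discovery rate control into binary networks (static before/after
    networks or sliding-window dynamic networks), and trial-resampling
    bootstraps provide per-edge appearance probabilities and confidence
    intervals for network density. A synthetic-session simulator with known
    ground-truth networks (1/f background, band-limited correlated
    components, variance-preserving trial windows) supports verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
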