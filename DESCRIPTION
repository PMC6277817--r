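Package: thetanest
Title: Single-Cycle Profiling of Hippocampal Theta Oscillations by Nested
    Spectral Components
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised decomposition of hippocampal local field
    potentials (LFPs) into theta-nested spectral components (tSCs).
    Raw LFPs are split by ensemble empirical mode decomposition (EEMD)
    into low-frequency, theta (5-12 Hz) and supra-theta signals;
    individual theta cycles are detected and phase-referenced; per-cycle
    Morlet wavelet spectral signatures (10-200 Hz) are decomposed by
    PCA plus FastICA into tSCs whose per-cycle strength is the
    projection of the cycle signature onto the component.  Downstream
    statistics cover spike-phase coupling with circular-shift nulls,
    cross-validated GLM prediction of tSC strength from ensemble spike
    counts, sharp-wave/ripple (SWR) co-firing reactivation regressions,
    current source density laminar profiles, and task-stage modulation
    models.  A synthetic-data module generates LFPs, spike trains,
    behavior and rest epochs with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
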