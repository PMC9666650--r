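Package: vection
Title: Motion-Onset ERP Analysis of Vection-Consistent Visual Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of motion-onset event-related potentials
    (ERPs) elicited by vection-consistent (coherent) versus
    vection-inconsistent (incoherent) rotating dot fields. Provides a
    BrainVision reader/writer, optic-flow dot-field stimulus kinematics,
    a synthetic multi-subject EEG and behaviour generator, the full
    preprocessing chain (notch/band-pass filtering, common-average
    re-referencing, epoching, baseline correction, sliding-window artifact
    rejection, participant inclusion rules), window mean-amplitude ERP
    measures, spatial cluster-based permutation tests for condition and
    handedness contrasts, Wilcoxon rank-sum behavioural comparisons with
    r = Z/sqrt(N) effect sizes, and Spearman brain-behaviour correlations,
    orchestrated by a deterministic pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
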