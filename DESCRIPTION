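Package: flychrono
Title: Sleep, Circadian Activity and Survival Analysis for Drosophila
    Activity Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads and validates TriKinetics Drosophila Activity Monitor
    (DAM) beam-break recordings, scores sleep (five minutes of inactivity),
    rest bouts, wake activity and death (more than 24 hours of terminal
    inactivity) for each fly, builds population activity and sleep profiles
    in Zeitgeber time with anticipation indices and double-plotted actogram
    matrices, and computes the accompanying statistics: Kaplan-Meier
    survival curves with median survival, the two-group Mantel-Haenszel
    (log-rank) test, eclosion-proportion and cell-count comparisons, and
    threshold-based differential-expression set overlaps. A synthetic-data
    generator produces DAM-format recordings with ground-truth sleep states
    and death times from a two-state sleep/wake Markov chain gating an
    inhomogeneous Poisson activity process, so every scoring rule can be
    checked against programmed truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
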