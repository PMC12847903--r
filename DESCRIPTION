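Package: sigscore
Title: Gut Dysbiosis Scoring with Species Interacting Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gut metagenomes as eubiotic or dysbiotic from the
    counts of detected taxa belonging to two antagonistic species
    interacting groups (SIG1, 37 resistance-associated species; SIG2, 45
    health-associated species), using an unweighted score
    S = (N_SIG2/45 - N_SIG1/37 + 1)/2 with fixed decision thresholds and an
    Akkermansia muciniphila gray-zone arbiter. Also provides MetaPhlAn-style
    abundance-table ingestion with centered log-ratio transforms,
    co-abundance network reconstruction with Ward-linkage clustering,
    retrospective cohort statistics (classification contrasts, survival
    correlations, median-split Kaplan-Meier analyses, rank-based
    differential abundance, compositional dysbiosis subtyping), and a
    calibrated synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    survival,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
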