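Package: decaypatterns
Title: Genome-Wide RNA Degradation Kinetics from Actinomycin-D Chase Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies actinomycin-D chase time courses of RNA abundance by
    density-peak clustering, fits a nested family of first-order exponential
    decay models with AIC selection, ranks kinetic clusters by degradation
    rate, categorizes genes as quick, slow or stable, clusters genes by their
    degradation-pattern profiles, and discovers de novo primary-sequence and
    secondary-structure motifs in 3' UTRs with over-representation statistics.
    Includes a ground-truthed synthetic-data generator emulating a stimulation
    by chase two-way time-course design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    limma,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
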