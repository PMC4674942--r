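Package: termensemble
Title: Unsupervised Medical Term Extraction with a Genetic-Algorithm Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts single- and multi-word medical terms from collections of
    short clinical letters without supervised training. Three complementary
    unsupervised extractors are provided: frequent-sequence mining
    (PrefixSpan), the C-Value termhood measure over noun-phrase candidates,
    and TextRank ranking on a sentence co-occurrence graph. Extracted
    rankings are cleaned against a domain dictionary and fused by a weighted
    sum over rank-normalised scores; the fusion weights are learnt with a
    genetic algorithm that maximises F-measure against a small annotated term
    set. A seeded synthetic clinical-letter generator with planted ground
    truth makes the whole pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
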