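Package: consensusDR
Title: Stage-Specific Consensus Drug Repurposing with Structural and
    Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for transcriptomic
    signature-reversal drug repurposing across disease stages.
    Extracts differential-expression signatures (moderated t-statistic,
    probe collapsing, symmetric top-150 up/down gene lists), aggregates
    ranked drug lists from multiple repurposing tools and datasets with a
    two-level weighted consensus score, performs hypergeometric
    over-representation analysis for pathways and drug targets, screens
    and clusters chemical fingerprints by Tanimoto similarity and Soergel
    distance, and scores drug-combination dose-response surfaces under
    four synergy reference models (ZIP, Loewe, HSA, Bliss). Includes
    seeded synthetic-data generators with planted ground truth for every
    input type, enabling end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    fgsea,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
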