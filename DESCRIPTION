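Package: entrainr
Title: Verbal Entrainment Analysis for Dyadic Task-Oriented Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conversational entrainment between two speakers in
    task-oriented dialogue across prosodic, lexical, syntactic, and semantic
    domains. Stylizes F0 and energy contours at the dialog-act and
    salient-syllable levels, scores turn-by-turn lexical, part-of-speech
    bigram, and embedding-based alignment, builds surrogate-dyad resampling
    baselines, reduces prosodic distance variables by exploratory and
    confirmatory factor analysis, and classifies each group as entraining,
    disentraining, or neither per linguistic domain using linear mixed-effects
    contrasts. Includes a synthetic dyad generator with ground-truth coupling
    parameters so the full pipeline is testable without audio recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
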