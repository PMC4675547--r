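Package: convrecur
Title: Conceptual Recurrence and Content-Based Engagement Analysis for
    Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing content-based conversational engagement in
    annotated two-speaker transcripts, such as conversations between people
    with dementia and care staff. Parses speaker-turn transcripts carrying
    inline behaviour codes, computes term-based turn-by-turn recurrence
    (binary cosine similarity over a capped, stopword-filtered
    per-conversation vocabulary) and the twelve windowed recurrence metrics
    (short/medium/long x forward/backward x self/other), derives binary
    engagement labels with range-isolation rules, and quantifies
    behaviour-engagement associations through 2x2 odds ratios with Wald
    intervals and univariate logistic regression. Includes a synthetic
    dyadic-conversation generator with known injected effects for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
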