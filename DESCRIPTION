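Package: saltalm
Title: Automated Language Measures from SALT-Style Conversation Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seven automated language measures (ALMs) from
    SALT-dialect transcripts of examiner-child conversation: mean length of
    utterance in morphemes, number of different word roots, um proportion,
    content maze proportion, unintelligible proportion, c-units per minute,
    and repetition proportion (echo of the examiner's previous turn under
    approximate matching). Provides centile-based ordinal recoding of raw
    measures onto a common 1-4 impairment scale, a cohort validation battery
    (Kruskal-Wallis with rank eta-squared, Games-Howell post-hoc contrasts,
    Spearman correlation matrices, age- and IQ-adjusted logistic
    classification with Wald tests, Nagelkerke R-squared, and ROC/AUC), and
    a synthetic examiner-child cohort generator so the entire pipeline can
    be exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
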