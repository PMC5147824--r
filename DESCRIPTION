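Package: cvfluency
Title: Computerized Scoring of Verbal Fluency Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of timestamped verbal-fluency transcripts.
    Computes classical correct-word and repetition scores, lexical measures
    (log word frequency, syllable count, cohort typicality), temporal
    production curves and the temporal decline percentage, concept-vector
    semantic measures (pairwise and all-pair cosine similarity, the semantic
    organization index, threshold-based switch and cluster statistics),
    Troyer-style subcategory switch and cluster analysis for the "animals"
    category, demographic-adjusted normative z-scores, and a multi-sign
    performance-validity (malingering) index. Includes generators for
    synthetic concept spaces and cohorts with planted structure, and a
    command-line report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
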