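---
title: "Scoring verbal fluency transcripts: measures, models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring verbal fluency transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfluency)
```

## The measurement problem

In a verbal fluency (VF) test a subject produces as many words as possible
from a semantic category ("animals") or beginning with a letter ("F")
during a fixed period; `cvfluency` assumes the 90-s computerized format in
which each word's onset time is logged.  The traditional score is the
number of *correct words* (CW): total words minus repetitions and
out-of-category words.  CW alone conflates several retrieval processes, so
the package computes a panel of ancillary measures — lexical, temporal,
and semantic — that describe *how* the words were retrieved, plus
demographic-adjusted z-scores and a performance-validity index built from
the panel.

## Scoring model

A transcript is an ordered sequence of normalized tokens with onsets.
Scoring partitions the words observed in a half-open window `[0, w)` into
correct, repeated, and out-of-category classes:

* **Repetition** is an exact string match against any earlier token.  No
  stemming is applied: "dog" and "dogs" are distinct responses, because an
  automatic scorer should not silently decide morphology; an optional
  `variant_map` lets a user collapse variants explicitly.
* A word that is both repeated and out of category is counted once, as
  out-of-category, so the three classes always partition the total.
* The repetition percentage uses total words as its denominator, which
  bounds it in [0, 100] for any input.
* Multi-word responses are joined with hyphens ("red fox" → "red-fox"),
  matching the token style of word-association databases.
* Window membership is `onset < w` (half-open), so a word begun exactly at
  60.0 s is outside a 60-s rescoring window.  The same convention applies
  to 15-s production bins and to the first-half window of the temporal
  decline percentage.
* Subcategory names co-occurring with their members ("fish" and "trout")
  are both accepted; scoring practice differs between laboratories, and
  suppression rules are a property of the supplied lexicon, not the
  scorer.  Ambiguous responses ("dinosaur") are likewise adjudicated
  entirely by the lexicon.

## Lexical measures

* **LWF** — mean log10 corpus frequency of the words produced.  Base 10 is
  used because published mean values (~3.6–3.8 on raw corpus counts) are
  consistent with log10.  Tokens missing from the frequency table are
  imputed at the table's minimum count, which avoids infinite values while
  preserving the "rare word" interpretation.
* **Syllable count** — dictionary lookup when a pronunciation lexicon is
  configured, otherwise a deterministic orthographic heuristic (maximal
  `aeiouy` groups, minus one for a terminal consonant + "e", floored at
  one per hyphen-separated part).  The heuristic is intentionally simple
  and transparent; it is exact for the vast majority of animal names.
* **Typicality** — within a cohort, each word's producer count (how many
  subjects produced it, at most once per subject); a subject's typicality
  is the *median* producer count of their words divided by the cohort
  size, expressed as a percentage.  The median is used because producer
  counts are heavily right-skewed.  Words absent from the cohort table
  count as produced by one subject (the subject under analysis).

Repetitions and out-of-category words are *included* in lexical means by
default (a `correct_only` flag restricts them), mirroring the convention
that all produced words enter semantic and lexical analyses.

## Temporal measures

Words are tallied in 15-s bins, and the **temporal decline percentage
(TDP)** is the percentage of words produced in the first half of the test.
A flat production rate gives TDP ≈ 50; healthy adults typically show ~63.
TDP uses all scored words by default, with a correct-only variant
reported alongside, since the definition ("words retrieved") does not
specify the exclusion of repetitions.  No voice-onset latency correction
is applied: keyboard-logged onsets are treated as the measurement.

## Concept-vector semantics

Semantic relatedness between two words is the cosine of their sparse
non-negative concept vectors (an explicit-semantic-analysis style
representation; the package reads any token → (concept, weight) TSV or a
precomputed pairwise-cosine cache).  From the cosines:

* **PW-ESA** — mean cosine of successive word pairs (retrieval order
  matters).
* **A-ESA** — mean cosine over all unordered position pairs: the expected
  PW-ESA if the same words were produced in random order.  Repeated
  tokens are kept as separate positions by default (cross-position
  self-pairs contribute 1); a `distinct_types` switch collapses them,
  since either convention is defensible.
* **SOI** = PW-ESA / A-ESA.  SOI > 1 means successive words are more
  related than chance ordering of the same words: semantically organized
  retrieval.  Unlike switch counts, SOI is not arithmetically coupled to
  CW.
* **Switches** — a switch precedes word *i+1* when
  `cos(w_i, w_{i+1}) < f × A-ESA`, with strict inequality ("fell below")
  and default fraction `f = 0.75`, the operating point at which
  threshold-based switch counts align with subcategory-based counts.  The
  fraction is exposed everywhere (function argument and CLI flag) to
  reproduce the 1.00 / 0.75 / 0.50 sweep.
* **Clusters** — maximal runs between switches; sizes partition N and
  `n_clusters = n_switches + 1`.  Multi-word clusters have ≥ 2 words, and
  mean cluster size is averaged over multi-word clusters only (reported 0
  when none exist).

Tokens missing from the concept store are dropped from semantic
computations with a warning and a reported coverage fraction; dropping
preserves the validity of the remaining cosines, whereas any imputation
would fabricate relatedness.

## Subcategory (Troyer-style) analysis

For the "animals" category the package bundles a 22-subcategory
membership table (living environment, human use, taxonomy).  A switch is a
transition between adjacent words sharing *no* subcategory — the pairwise
chaining rule, which reproduces the canonical seven-word example
("rabbit, cat, tiger, lion, zebra, crocodile, whale" → 0 switches)
because each adjacent pair shares a label even though no single label
spans the run.  "Tiger" is deliberately retained in the African
subcategory to match common (if zoologically wrong) scoring practice.
Cluster sizes are counted in words, not the size-minus-one convention, so
multi-word cluster sizes are directly comparable with the concept-vector
clusters.  Unknown tokens have empty membership and therefore switch on
both sides; the table is a user-extensible TSV.

## Normative model and z-scores

Correct-word scores are adjusted for education and daily computer use
(Likert 1–8) with linear regressions; the bundled defaults are the
published 90-s equations

    semantic: CW = 10.61 + 0.781·Education + 0.912·Computer-use
    phonemic: CW =  9.65 + 0.356·Education + 0.789·Computer-use

and z = (observed − predicted) / residual SD.  The residual SDs are not
published directly; the defaults derive them from the cohort SDs (6.9,
6.5) and the regression R² (17.0%, 8.5%) as SD·√(1−R²) ≈ 6.29 and 6.22.
Abnormality is one-tailed (deficit direction): z below the α = 0.05
normal quantile, −1.645.  `fit_norms()` refits the whole model (OLS plus
empirical thresholds) to any local control cohort; nearest-rank (inverse
ECDF) percentiles are used for the control-tail thresholds because the
estimator is simple, monotone, and defined for small cohorts.  The
bundled default thresholds are normal-tail approximations from the
published cohort means and SDs — adequate for demonstration, but a local
control cohort should be preferred for clinical-style use.

## Malingering index

Six binary signs compare a semantic-condition panel against the control
distribution: five response-style signs add one point each — short words
(mean syllables ≤ the lower p10), frequent words (LWF ≥ p90), typical
words (typicality ≥ p90), many repetitions (repeat % ≥ p90), and an SOI
*inside* the normal range (> mean − 1 SD) — while an abnormally steep
temporal decline (TDP ≥ p90), characteristic of genuine impairment,
subtracts one.  The aggregation (five +1 terms, one −1 term, range −1..5)
is the unique linear rule consistent with every row of the published sign
panel bundled as `malingering_signs_fixture()`.  Signs fire at the
p ≤ 0.10 tail by default because both 0.05- and 0.10-tail entries enter
the published totals.  The default decision rule flags an index ≥ 3; on
the bundled panel this gives 80% sensitivity and 89% specificity,
recomputed (not stored) by the test suite.  One numeric caveat: the
published z-cutoff −2.5 specificity is the fraction 8/9 = 88.9%, printed
as 88 in one place and the identical fraction as 89 elsewhere; the tests
therefore check the exact fraction to integer-rounding ambiguity.

## Synthetic data: what it emulates, and what it does not

`make_toy_concept_space()` builds vectors as weighted sums of three
orthogonal axes (global, cluster, word-unique), so same-cluster and
cross-cluster cosines hit their targets *exactly* (defaults 0.9 / 0.1);
the seed only rescales vectors, which is cosine-invariant.
`simulate_transcript()` performs a retrieval walk over the planted
clusters: runs within a cluster, jumps with `cluster_switch_prob`,
repeats with `repeat_prob`, and onsets drawn from a piecewise-constant
density declining by `rate_decay` per 15-s bin (an inhomogeneous Poisson
profile conditioned on the word count).  Defaults are fixed at the study
conditions for a healthy adult on the 90-s semantic test: 27 distinct
words, switch probability 0.35 (≈ 9 switches per transcript),
`rate_decay = 0.84` (first-half share 1/(1+0.84³) ≈ 63%), repeat
probability 0.013 (≈ 1.3% repetitions).  The malingering profile (15
words, repeat probability 0.15, flat hazard, typicality bias 2) emulates
the observed feigned style — short typical words, frequent repetition, no
temporal decline — and is an emulation of that pattern, not a model of
malingerer psychology.

What passing tests on synthetic data show: the estimators recover planted
structure — switch boundaries exactly on high-contrast spaces, regression
slopes within ±0.15 at n = 500, TDP ≈ 50 under a flat hazard.  What they
do not show: real transcripts have graded, heavy-tailed cosine structure,
category-dependent lexicons, and correlated demographics, none of which
the generator reproduces; cohort-level means from real populations are
therefore out of reach of the simulator by design.

## Numerical choices and degenerate inputs

* Ties in onset times keep input order (stable sort); simultaneous onsets
  yield zero interword intervals.
* Empty transcripts score all-zero; TDP and typicality are *signalled*
  as errors on empty input rather than returning a number.
* Cosines are clipped at 1 against floating-point drift; zero vectors are
  rejected at store construction and again at use.
* A-ESA = 0 makes the SOI undefined (signalled), and switch detection
  with threshold fraction ≤ 0 is a parameter error.
* All-singleton clusterings report mean multi-word cluster size 0.
* Problem sizes in the test suite (500-subject cohorts, 2000-shuffle
  Monte-Carlo checks, 200-seed TDP averages) were chosen as the smallest
  sizes at which the stated tolerances are comfortably stable.

## Limitations

The bundled frequency table is synthetic demonstration data (real corpus
counts should be supplied for real use); the bundled concept-space
generator is a planted-structure surrogate, not a trained semantic model;
the default norms assume the published cohort's demographics and normal
control tails; and no claim of clinical validity is made for the
malingering index outside the reproduced panel.
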