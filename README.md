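# cvfluency

Automated scoring of timestamped verbal-fluency transcripts.

## The problem

Verbal fluency (VF) tests — "name as many animals as you can", or "as many
words starting with F" — are among the most widely used neuropsychological
tests, but hand scoring captures only the correct-word total and misses
*how* the words were retrieved.  Given a computerized transcript (ordered
word tokens with onset times over a 90-s test), `cvfluency` computes the
full analysis panel for researchers and clinicians working with
computerized VF data:

* **Scoring** — correct words `CW = total − repetitions −
  out-of-category`, repetition percentage, re-scoring over any window
  (e.g. the first 60 s).
* **Lexical** — mean log10 word frequency (LWF), mean syllable count, and
  cohort typicality (median producer count / cohort size, as a percent).
* **Temporal** — words per 15-s bin, interword intervals, and the temporal
  decline percentage (TDP): the percent of words produced in the first
  half of the test.
* **Semantic (concept vectors)** — cosine similarity between words'
  sparse concept vectors: mean adjacent-pair cosine (PW-ESA), mean
  all-pair cosine (A-ESA), the semantic organization index
  `SOI = PW-ESA / A-ESA`, switches (adjacent cosine `< 0.75 × A-ESA`),
  and multi-word cluster statistics.
* **Semantic (subcategories)** — Troyer-style switch/cluster analysis for
  the "animals" category using a bundled 22-subcategory table.
* **Norms** — demographic-adjusted z-scores via
  `CW = b0 + b1·Education + b2·Computer-use` (bundled published
  coefficients, or refit with `fit_norms()` on a local control cohort),
  with one-tailed abnormality at z < −1.645.
* **Performance validity** — a six-sign malingering index (short /
  frequent / typical / repeated words, normal-range SOI, each +1; steep
  temporal decline −1) with cutoff classification and
  sensitivity/specificity evaluation.
* **Simulation** — toy concept spaces with exact planted cosine
  structure, synthetic transcripts with controllable clustering, temporal
  decay, repetition rate, and malingering profiles, and cohort generators
  with a known normative model for parameter-recovery testing.

## Worked example

```r
library(cvfluency)

tr   <- read_transcript_csv(system.file("extdata", "example_transcript.csv",
                                        package = "cvfluency"))
rule <- category_rule("lexicon", lexicon = read_token_list(
          system.file("extdata", "animals_lexicon.txt", package = "cvfluency")))
freq <- read_frequency_table(system.file(
          "extdata", "word_frequencies_synthetic.tsv", package = "cvfluency"))

analyze(tr, rule, freq_table = freq, subcat_table = troyer_table(),
        norms = default_norms())
#> <cvf_fluency_report> demo01 | semantic (animals)
#>   correct 20 / total 21 | repeats 4.8% | out 0
#>   LWF 2.62 | Syll 1.48 | Typ NA
#>   TDP 61.9%
#>   Troyer switches 5 | multi-word clusters 5 (mean 4.0)
#>   z -1.36 (normal)
#>   not computed: esa, signs
```

The subject produced 21 words of which 20 were correct (one repetition of
"dog"), with 61.9% of words in the first 45 s (a typical decline), five
subcategory switches, and a correct-word score 1.36 residual SDs below the
education/computer-use-adjusted prediction — low but within normal limits.
Typicality is `NA` because it needs a cohort (see `cohort_analyze()`), and
the concept-vector block needs a semantic store:

```r
space <- make_toy_concept_space(4, 5, within_cosine = 0.9,
                                between_cosine = 0.1, seed = 1)
tr2 <- simulate_transcript(sim_profile(n_words = 15, repeat_prob = 0),
                           space, seed = 7)
es <- esa_summary(tr2$events$token, space)
#> PW-ESA 0.500 | A-ESA 0.268 | SOI 1.87 | switches 7 (planted 7)
```

SOI = 1.87 means successive words were nearly twice as related as a random
ordering of the same words, and the threshold detector recovered all seven
planted cluster boundaries.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cvf.R analyze transcript.csv --lexicon animals.txt \
    --norms builtin --out report.json
Rscript inst/cli/cvf.R cohort transcripts/ --lexicon animals.txt --labels labels.tsv
Rscript inst/cli/cvf.R simulate --seed 1 --n 20 --out simdir/
```

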