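test_that("analyze composes the panel from the module layers", {
  rule <- category_rule("lexicon", lexicon = c("dog", "cat"))
  tr <- quick_transcript(c("dog", "cat", "dog", "truck"), c(2, 5, 9, 14))
  ft <- frequency_table(c(dog = 100, cat = 50, truck = 800))
  rep <- analyze(tr, rule, freq_table = ft)
  expect_s3_class(rep, "cvf_fluency_report")
  expect_equal(rep$score$correct, 2L)
  expect_equal(rep$score$pct_repeats, 25.0)
  expect_equal(sum(rep$temporal$bin_counts), 4)
  # resources not supplied are flagged, not fatal
  expect_true(all(c("esa", "troyer", "z") %in% rep$not_computed))
  expect_null(rep$esa)
})

test_that("shrinking the window never raises the correct-word score", {
  rule <- small_rule()
  for (seed in 1:6) {
    tr <- random_transcript(15, seed)
    cw60 <- analyze(tr, rule, window_s = 60)$score$correct
    cw90 <- analyze(tr, rule, window_s = 90)$score$correct
    expect_lte(cw60, cw90)
  }
})

test_that("identical invocations produce byte-identical reports", {
  sp <- make_toy_concept_space(3, 5, seed = 2)
  rule <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))
  tr <- simulate_transcript(sim_profile(n_words = 10, repeat_prob = 0),
                            sp, seed = 4)
  ft <- frequency_table(c(a = 10), source_label = "toy")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(analyze(tr, rule, freq_table = ft, store = sp), f1)
  write_report_json(analyze(tr, rule, freq_table = ft, store = sp), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reports round-trip through JSON", {
  rule <- small_rule()
  tr <- quick_transcript(c("dog", "cat", "lion"), c(1, 30, 70),
                         age = 40, education = 14, computer_use = 5)
  rep <- analyze(tr, rule, norms = default_norms())
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- read_report_json(path)
  expect_equal(back$score$correct, rep$score$correct)
  expect_equal(back$z$z, rep$z$z, tolerance = 1e-12)
  expect_equal(back$temporal$tdp, rep$temporal$tdp)
  expect_equal(unlist(back$provenance$window_s), rep$provenance$window_s)
})

test_that("z-scoring inside analyze matches the norms arithmetic", {
  rule <- small_rule()
  tr <- quick_transcript(c("dog", "cat", "lion"), c(1, 5, 9),
                         education = 14, computer_use = 5)
  rep <- analyze(tr, rule, norms = default_norms())
  nm <- default_norms()
  expect_equal(rep$z$predicted_cw, predict_cw(14, 5, "semantic", nm))
  expect_equal(rep$z$z,
               (3 - rep$z$predicted_cw) / nm$semantic$residual_sd)
  expect_true(rep$z$abnormal)  # 3 words is far below prediction
})

test_that("cohort analysis computes typicality first and labels reports", {
  # single-subject cohort: every word was produced by the whole cohort
  rule <- small_rule()
  solo <- cohort_analyze(list(quick_transcript(c("dog", "cat"), c(1, 4))),
                         rule)
  expect_equal(solo$reports[[1]]$lexical$typicality_pct, 100)
  expect_equal(solo$typicality_table$n_subjects, 1L)

  # mixed cohort with labels: the sign-based classifier is evaluated
  sp <- make_toy_concept_space(8, 6, seed = 31)
  lex <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))
  ft <- frequency_table(stats::setNames(
    rep(100, length(attr(sp, "cluster"))), names(attr(sp, "cluster"))))
  ts <- c(
    lapply(1:3, function(s) simulate_transcript(
      malingering_profile(), sp, subject_id = paste0("m", s), seed = s)),
    lapply(4:6, function(s) simulate_transcript(
      sim_profile(), sp, subject_id = paste0("c", s), seed = s)))
  ca <- cohort_analyze(ts, lex, freq_table = ft, store = sp,
                       norms = default_norms(),
                       labels = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_s3_class(ca$classifier, "cvf_classifier_eval")
  expect_equal(with(ca$classifier, tp + fn + tn + fp), 6)
  expect_equal(nrow(ca$summary), 6L)
  expect_true(all(!is.na(ca$summary$mi_total)))
})

test_that("cohort analysis can fit its own norms", {
  sp <- make_toy_concept_space(8, 6, seed = 37)
  lex <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))
  co <- simulate_cohort(40, sp, seed = 41)
  ca <- cohort_analyze(co$transcripts, lex, norms = "fit")
  expect_s3_class(ca$norms, "cvf_norms_model")
  # fitted prediction at the cohort means equals the cohort mean CW
  expect_equal(predict_cw(mean(ca$summary$education),
                          mean(ca$summary$computer_use), "semantic",
                          ca$norms),
               mean(ca$summary$cw), tolerance = 1e-9)
  expect_true(all(is.finite(ca$summary$z)))
})

test_that("the bundled example transcript analyzes end to end", {
  tr <- read_transcript_csv(system.file("extdata", "example_transcript.csv",
                                        package = "cvfluency"))
  ft <- read_frequency_table(system.file(
    "extdata", "word_frequencies_synthetic.tsv", package = "cvfluency"))
  rep <- analyze(tr, animals_rule(), freq_table = ft,
                 subcat_table = troyer_table(), norms = default_norms())
  expect_equal(rep$score$total, 21L)
  expect_equal(rep$score$repeats, 1L)   # "dog" reappears at 75.2 s
  expect_equal(rep$score$correct, 20L)
  expect_true(rep$troyer$n_switches > 0)
  expect_false(rep$z$abnormal)
  expect_output(print(rep), "correct 20 / total 21")
  row <- report_row(rep)
  expect_equal(row$correct, 20)
  expect_true(is.na(row$soi))  # no concept store supplied
})

test_that("the command-line front end scores a transcript file", {
  script <- system.file("cli", "cvf.R", package = "cvfluency")
  out <- withr::local_tempfile(fileext = ".json")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(script, "analyze",
                   system.file("extdata", "example_transcript.csv",
                               package = "cvfluency"),
                   "--lexicon", system.file("extdata",
                                            "animals_lexicon.txt",
                                            package = "cvfluency"),
                   "--norms", "builtin", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(is.null(attr(res, "status")) ||
                identical(attr(res, "status"), 0L))
  rep <- read_report_json(out)
  expect_equal(rep$score$correct, 20)
})
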