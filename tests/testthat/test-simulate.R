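test_that("toy concept spaces hit their cosine targets exactly", {
  sp <- make_toy_concept_space(4, 5, 0.9, 0.1, seed = 1)
  labels <- attr(sp, "cluster")
  expect_length(labels, 20L)
  toks <- names(labels)
  set.seed(1)
  within <- between <- numeric(0)
  for (rep in 1:40) {
    pair <- sample(toks, 2)
    cs <- cosine(sp$vectors[[pair[1]]], sp$vectors[[pair[2]]])
    if (labels[pair[1]] == labels[pair[2]]) within <- c(within, cs)
    else between <- c(between, cs)
  }
  expect_true(all(abs(within - 0.9) < 1e-9))
  expect_true(all(abs(between - 0.1) < 1e-9))
  # single cluster: everything is within-cluster
  sp1 <- make_toy_concept_space(1, 4, 0.8, 0.0, seed = 2)
  v <- sp1$vectors
  expect_true(all(combn(names(v), 2, function(p)
    cosine(v[[p[1]]], v[[p[2]]])) >= 0.8 - 1e-9))
  # determinism and infeasibility
  expect_identical(make_toy_concept_space(3, 3, seed = 7),
                   make_toy_concept_space(3, 3, seed = 7))
  expect_error(make_toy_concept_space(2, 2, 0.5, 0.6), "between_cosine <")
})

test_that("simulated transcripts respect their profile knobs", {
  sp <- make_toy_concept_space(6, 6, seed = 4)
  rule <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))

  # repeat_prob 0 -> no repetitions, exact word count
  tr <- simulate_transcript(sim_profile(n_words = 20, repeat_prob = 0),
                            sp, seed = 10)
  s <- score_transcript(tr, rule)
  expect_equal(s$repeats, 0L)
  expect_equal(s$correct, 20L)

  # cluster_switch_prob 0 -> a single planted run per cluster; on a
  # high-contrast space the detector finds exactly the planted switches
  tr0 <- simulate_transcript(
    sim_profile(n_words = 12, cluster_switch_prob = 0, repeat_prob = 0),
    sp, seed = 11)
  es <- esa_summary(tr0$events$token, sp)
  expect_equal(es$switch_positions, attr(tr0, "planted_switches"))

  # determinism
  expect_identical(
    simulate_transcript(sim_profile(n_words = 15), sp, seed = 3)$events,
    simulate_transcript(sim_profile(n_words = 15), sp, seed = 3)$events)

  # lexicon exhaustion truncates with a warning
  tiny <- make_toy_concept_space(2, 2, seed = 5)
  expect_warning(trunc <- simulate_transcript(
    sim_profile(n_words = 10, repeat_prob = 0), tiny, seed = 6),
    "exhausted")
  expect_lte(nrow(trunc$events), 4L)
})

test_that("planted switches are recovered across random seeds", {
  sp <- make_toy_concept_space(5, 8, 0.9, 0.1, seed = 21)
  for (seed in 1:8) {
    tr <- simulate_transcript(
      sim_profile(n_words = 18, cluster_switch_prob = 0.4,
                  repeat_prob = 0), sp, seed = seed)
    es <- esa_summary(tr$events$token, sp)
    expect_equal(es$switch_positions, attr(tr, "planted_switches"),
                 info = paste("seed", seed))
  }
})

test_that("a flat hazard gives TDP near 50; decay raises it", {
  sp <- make_toy_concept_space(6, 6, seed = 9)
  mean_tdp <- function(decay, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulate_transcript(
        sim_profile(n_words = 20, rate_decay = decay, repeat_prob = 0),
        sp, seed = s)
      tdp(tr)
    }, numeric(1)))
  }
  flat <- mean_tdp(1.0, 1:200)
  expect_lt(abs(flat - 50), 3)
  decayed <- mean_tdp(0.84, 1:100)
  expect_gt(decayed, flat + 5)  # planted decay shows up in the TDP
})

test_that("simulated cohorts let fit_norms recover the planted model", {
  sp <- make_toy_concept_space(8, 6, seed = 13)
  co <- simulate_cohort(500, sp, seed = 17)
  rule <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))
  cw <- vapply(co$transcripts,
               function(t) score_transcript(t, rule)$correct, numeric(1))
  # scored correct words equal the planted targets
  expect_equal(cw, co$truth$cw)
  df <- data.frame(cw = cw, education = co$truth$education,
                   computer_use = co$truth$computer_use)
  nm <- fit_norms(df, "semantic")
  expect_lt(abs(nm$semantic$coef_education - 0.8), 0.15)
  expect_lt(abs(nm$semantic$coef_computer_use - 0.9), 0.15)
})

test_that("clustered retrieval has higher SOI than shuffled retrieval", {
  sp <- make_toy_concept_space(6, 6, seed = 23)
  sois <- vapply(1:20, function(s) {
    tr <- simulate_transcript(
      sim_profile(n_words = 15, cluster_switch_prob = 0.3,
                  repeat_prob = 0), sp, seed = s)
    toks <- tr$events$token
    set.seed(s + 1000)
    c(clustered = soi(toks, sp), shuffled = soi(sample(toks), sp))
  }, numeric(2))
  expect_gt(mean(sois["clustered", ]), mean(sois["shuffled", ]))
  expect_equal(mean(sois["shuffled", ]), 1, tolerance = 0.1)
})

test_that("malingering profile emulates the feigned response style", {
  sp <- make_toy_concept_space(8, 6, seed = 29)
  rule <- category_rule("lexicon", lexicon = names(attr(sp, "cluster")))
  reps <- vapply(1:30, function(s) {
    tr <- simulate_transcript(malingering_profile(), sp, seed = s)
    score_transcript(tr, rule)$pct_repeats
  }, numeric(1))
  base <- vapply(1:30, function(s) {
    tr <- simulate_transcript(sim_profile(), sp, seed = s + 500)
    score_transcript(tr, rule)$pct_repeats
  }, numeric(1))
  expect_gt(mean(reps), mean(base))
  # flat hazard: TDP centred near 50 rather than the declining default
  mal_tdp <- mean(vapply(1:60, function(s)
    tdp(simulate_transcript(malingering_profile(), sp, seed = s)),
    numeric(1)))
  expect_lt(abs(mal_tdp - 50), 5)
})
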