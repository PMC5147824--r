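test_that("cosine of sparse non-negative vectors lies in [0, 1]", {
  u <- c(x = 1, y = 1)
  expect_equal(cosine(u, u), 1.0)
  expect_equal(cosine(c(x = 1), c(y = 2)), 0)          # disjoint support
  expect_equal(cosine(u, c(x = 1)), 1 / sqrt(2), tolerance = 1e-6)
  expect_error(cosine(u, c(x = 0, y = 0)), "zero vector")
})

test_that("adjacent cosine series follows the store", {
  st <- abc_store()
  expect_equal(pw_esa_series(c("a", "b", "c"), st), c(0.6, 0.4))
  expect_equal(pw_esa_series(c("a", "a"), st), 1.0)  # repeats are identical
  expect_error(pw_esa_series("a", st), "at least two")
})

test_that("all-pair mean is order-free and includes repeat positions", {
  st <- abc_store()
  expect_equal(a_esa(c("a", "b", "c"), st), 0.4)
  # permutation invariance
  expect_equal(a_esa(c("c", "a", "b"), st), 0.4)
  # repeated tokens kept as positions: pairs (a,a)=1, (a,b)=.6 twice
  expect_equal(a_esa(c("a", "a", "b"), st), (1 + 0.6 + 0.6) / 3)
  # collapsing to types drops the self-pair
  expect_equal(a_esa(c("a", "a", "b"), st, distinct_types = TRUE), 0.6)
})

test_that("SOI is the PW/A ratio, 1 when all cosines are equal", {
  same <- cache_store(c("a", "a", "b"), c("b", "c", "c"), rep(0.37, 3))
  expect_equal(soi(c("a", "b", "c"), same), 1.0)
  st <- abc_store()
  expect_equal(soi(c("a", "b", "c"), st), 0.5 / 0.4)
  zero <- cache_store(c("a", "a", "b"), c("b", "c", "c"), rep(0, 3))
  expect_error(soi(c("a", "b", "c"), zero), "zero")
})

test_that("mean PW-ESA over random shuffles converges to A-ESA", {
  space <- make_toy_concept_space(3, 4, 0.85, 0.15, seed = 11)
  tokens <- names(attr(space, "cluster"))[c(1:5, 9:12, 6)]  # 10 tokens
  a <- a_esa(tokens, space)
  set.seed(42)
  pws <- replicate(2000, pw_esa(sample(tokens), space))
  expect_lt(abs(mean(pws) - a), 0.02)
  # and hence the expected SOI of a shuffled transcript is ~1
  expect_equal(mean(pws) / a, 1, tolerance = 0.05)
})

test_that("switch detection thresholds at a fraction of the A-ESA", {
  st <- v5_store()
  toks <- paste0("v", 1:5)
  expect_equal(a_esa(toks, st), 0.5)
  # threshold 0.75 * 0.5 = 0.375: only the 0.1 pair falls below
  expect_equal(detect_switches(toks, st, 0.75), 4L)
  # limit: tiny fraction -> no switches
  expect_length(detect_switches(toks, st, 1e-9), 0L)
  expect_error(detect_switches(toks, st, 0), "positive")
})

test_that("switch count is non-decreasing in the threshold fraction", {
  space <- make_toy_concept_space(4, 4, 0.9, 0.1, seed = 3)
  set.seed(5)
  for (rep in 1:5) {
    toks <- sample(names(attr(space, "cluster")), 10)
    counts <- vapply(c(0.25, 0.5, 0.75, 1.0, 1.25),
                     function(f) length(detect_switches(toks, space, f)),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("cluster statistics partition the sequence", {
  cs <- cluster_stats(5, 4L)  # one switch before the 4th word
  expect_equal(cs$cluster_sizes, c(3, 2))
  expect_equal(cs$n_multiword_clusters, 2L)
  expect_equal(cs$mean_multiword_cluster_size, 2.5)

  expect_equal(cluster_stats(4, integer(0))$cluster_sizes, 4)
  all_sw <- cluster_stats(4, 2:4)
  expect_equal(all_sw$cluster_sizes, rep(1, 4))
  expect_equal(all_sw$n_multiword_clusters, 0L)
  expect_equal(all_sw$mean_multiword_cluster_size, 0)

  set.seed(8)
  for (rep in 1:10) {
    n <- sample(2:30, 1)
    sw <- sort(sample(2:n, sample(0:(n - 1), 1)))
    cs <- cluster_stats(n, sw)
    expect_equal(sum(cs$cluster_sizes), n)
    expect_equal(cs$n_clusters, length(sw) + 1L)
  }
  expect_error(cluster_stats(3, 5L), "2..n_tokens")
})

test_that("tokens missing from the store are dropped with coverage", {
  st <- abc_store()
  expect_warning(res <- resolve_tokens(c("a", "nope", "b"), st), "missing")
  expect_equal(res$tokens, c("a", "b"))
  expect_equal(res$coverage, 2 / 3)
})

test_that("semantic summary ties switches, clusters, and coverage together", {
  space <- make_toy_concept_space(3, 5, 0.9, 0.1, seed = 2)
  toks <- c(paste0("c1w", 1:3), paste0("c2w", 1:3), paste0("c3w", 1:3))
  es <- esa_summary(toks, space)
  expect_equal(es$n_switches, 2L)
  expect_equal(es$switch_positions, c(4L, 7L))
  expect_equal(es$cluster_sizes, c(3, 3, 3))
  expect_equal(es$n_switches + 1L, length(es$cluster_sizes))
  expect_equal(es$coverage, 1)
  expect_true(es$soi > 1)  # clustered order is semantically organized
  expect_true(es$pw_esa >= 0 && es$pw_esa <= 1)
  expect_true(es$a_esa >= 0 && es$a_esa <= 1)
})

test_that("concept stores load from TSV and cosine caches", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("token\tconcept_id\tweight",
               "dog\tk9\t1", "dog\tpet\t1", "wolf\tk9\t1"), tsv)
  st <- read_concept_store(tsv)
  expect_equal(cosine(st$vectors[["dog"]], st$vectors[["wolf"]]),
               1 / sqrt(2), tolerance = 1e-9)
  cache <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("token_a\ttoken_b\tcosine", "dog\twolf\t0.71"), cache)
  st2 <- read_cosine_cache(cache)
  expect_equal(pw_esa_series(c("wolf", "dog"), st2), 0.71)  # symmetric
})
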