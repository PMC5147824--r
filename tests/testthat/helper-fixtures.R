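# Shared fixtures, all built in code.

# Concept store backed by an explicit pairwise-cosine cache.
cache_store <- function(a, b, cosine) {
  concept_store(cosine_cache = data.frame(token_a = a, token_b = b,
                                          cosine = cosine))
}

# Three tokens with known pairwise cosines.
abc_store <- function() {
  cache_store(c("a", "a", "b"), c("b", "c", "c"), c(0.6, 0.2, 0.4))
}

# Five tokens whose adjacent cosines are [0.8, 0.7, 0.1, 0.9] and whose
# all-pair mean is exactly 0.5 (six non-adjacent pairs at 2.5/6).
v5_store <- function() {
  adj <- data.frame(token_a = c("v1", "v2", "v3", "v4"),
                    token_b = c("v2", "v3", "v4", "v5"),
                    cosine = c(0.8, 0.7, 0.1, 0.9))
  pairs <- t(utils::combn(paste0("v", 1:5), 2))
  nonadj <- pairs[abs(as.integer(substring(pairs[, 1], 2)) -
                        as.integer(substring(pairs[, 2], 2))) > 1L, ]
  rest <- data.frame(token_a = nonadj[, 1], token_b = nonadj[, 2],
                     cosine = 2.5 / 6)
  concept_store(cosine_cache = rbind(adj, rest))
}

# Quick transcript with evenly spaced onsets unless given.
quick_transcript <- function(tokens, onsets = NULL, duration_s = 90, ...) {
  if (is.null(onsets))
    onsets <- seq(1, by = 2, length.out = length(tokens))
  transcript("t1", "semantic", "animals", tokens, onsets,
             duration_s = duration_s, ...)
}

animals_rule <- function() {
  category_rule("lexicon", lexicon = read_token_list(
    system.file("extdata", "animals_lexicon.txt", package = "cvfluency")))
}

# Random transcript over a tiny mixed lexicon (some out-of-category, some
# repeats), for property tests.
random_transcript <- function(n, seed) {
  set.seed(seed)
  vocab <- c("dog", "cat", "lion", "trout", "truck", "chair")
  toks <- sample(vocab, n, replace = TRUE)
  quick_transcript(toks, sort(runif(n, 0, 90)))
}

small_rule <- function() {
  category_rule("lexicon", lexicon = c("dog", "cat", "lion", "trout"))
}
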