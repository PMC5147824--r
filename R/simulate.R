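with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a toy concept space with planted cluster structure
#'
#' Builds a [concept_store()] of `n_clusters * words_per_cluster` tokens
#' (named `c<i>w<j>`) whose pairwise cosines hit the requested targets
#' exactly: every vector is a weighted sum of three orthogonal axes — a
#' shared global axis (weight^2 = `between_cosine`), a cluster axis
#' (weight^2 = `within_cosine - between_cosine`), and a word-unique axis
#' (weight^2 = `1 - within_cosine`) — so same-cluster pairs have cosine
#' `within_cosine` and cross-cluster pairs `between_cosine`.  The seed
#' fixes the (cosine-invariant) random per-word scaling, making stores
#' bit-reproducible.
#'
#' @param n_clusters Number of planted clusters.
#' @param words_per_cluster Words per cluster.
#' @param within_cosine Target same-cluster cosine, in (`between_cosine`, 1].
#' @param between_cosine Target cross-cluster cosine, in [0, `within_cosine`).
#' @param seed Integer seed.
#' @return A `cvf_concept_store` with attribute `"cluster"` (named integer
#'   vector: token -> planted cluster id).
#' @examples
#' space <- make_toy_concept_space(4, 5, 0.9, 0.1, seed = 1)
#' @export
make_toy_concept_space <- function(n_clusters, words_per_cluster,
                                   within_cosine = 0.9,
                                   between_cosine = 0.1, seed = 1) {
  if (!(between_cosine >= 0 && between_cosine < within_cosine &&
        within_cosine <= 1))
    stop("require 0 <= between_cosine < within_cosine <= 1", call. = FALSE)
  with_seed(seed, {
    vecs <- list()
    labels <- integer(0)
    g <- sqrt(between_cosine)
    a <- sqrt(within_cosine - between_cosine)
    b <- sqrt(1 - within_cosine)
    for (i in seq_len(n_clusters)) {
      for (j in seq_len(words_per_cluster)) {
        tok <- sprintf("c%dw%d", i, j)
        v <- c(g, a, b) * stats::runif(1, 0.5, 2)  # scale is cosine-invariant
        names(v) <- c("g0", sprintf("c%d", i), sprintf("u_%s", tok))
        vecs[[tok]] <- v[v > 0]
        labels[tok] <- i
      }
    }
    store <- concept_store(vecs)
    attr(store, "cluster") <- labels
    store
  })
}

#' Simulation profile for synthetic transcripts
#'
#' Defaults emulate a healthy adult on the 90-s semantic test: about 27
#' distinct correct words, a switch between semantic clusters roughly every
#' third word, a production rate falling by a factor 0.84 per 15-s bin
#' (first-half share about 63%), and a ~1% repetition rate.
#'
#' @param n_words Target number of distinct (correct) words.
#' @param cluster_switch_prob Probability that the next distinct word comes
#'   from a new planted cluster.
#' @param rate_decay Per-bin hazard multiplier (<= 1); 1 = flat rate.
#' @param repeat_prob Probability, after each emission, of re-emitting an
#'   earlier word.
#' @param typicality_bias Preference weight for early (high-producer-count)
#'   words within a cluster: selection weight is `rank^(-bias)`; 0 =
#'   uniform.
#' @param duration_s Test duration in seconds.
#' @param age,education,computer_use Demographics copied to the transcript.
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @return A list of class `cvf_sim_profile`.
#' @export
sim_profile <- function(n_words = 27, cluster_switch_prob = 0.35,
                        rate_decay = 0.84, repeat_prob = 0.013,
                        typicality_bias = 0, duration_s = 90,
                        age = 40, education = 14.5, computer_use = 5,
                        seed = NULL) {
  stopifnot(cluster_switch_prob >= 0, cluster_switch_prob <= 1,
            repeat_prob >= 0, repeat_prob <= 1,
            rate_decay > 0, rate_decay <= 1, n_words >= 1)
  structure(list(n_words = n_words,
                 cluster_switch_prob = cluster_switch_prob,
                 rate_decay = rate_decay, repeat_prob = repeat_prob,
                 typicality_bias = typicality_bias, duration_s = duration_s,
                 age = age, education = education,
                 computer_use = computer_use, seed = seed),
            class = "cvf_sim_profile")
}

#' Simulation profile emulating feigned impairment
#'
#' Mirrors the response style observed in simulated malingerers: few words,
#' drawn from the most typical part of the lexicon, frequently repeated,
#' with a flat (decay-free) production rate.  An emulation of the observed
#' pattern, not a model of malingerer psychology.
#'
#' @param ... Overrides passed to [sim_profile()].
#' @return A `cvf_sim_profile`.
#' @export
malingering_profile <- function(...) {
  defaults <- list(n_words = 15, cluster_switch_prob = 0.5,
                   rate_decay = 1.0, repeat_prob = 0.15,
                   typicality_bias = 2)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_profile, args)
}

# onsets: i.i.d. draws from a piecewise-constant density declining by
# `decay` per 15-s bin (an inhomogeneous Poisson profile conditioned on N)
sample_onsets <- function(n, duration_s, decay, bin_width_s = 15) {
  n_bins <- max(1L, floor(duration_s / bin_width_s))
  mass <- decay^(seq_len(n_bins) - 1L)
  bin <- sample.int(n_bins, n, replace = TRUE, prob = mass)
  sort((bin - 1L + stats::runif(n)) * bin_width_s)
}

#' Simulate a single fluency transcript
#'
#' A retrieval walk over a planted-cluster concept space: distinct words
#' are emitted in runs within the current cluster, jumping to a fresh
#' cluster with probability `cluster_switch_prob` (or when the cluster is
#' exhausted); after each emission an earlier word may be re-emitted with
#' probability `repeat_prob`.  Onsets are drawn from a density declining by
#' `rate_decay` per 15-s bin, so `rate_decay = 1` gives a flat rate and an
#' expected temporal decline percentage of 50.
#'
#' @param profile A [sim_profile()].
#' @param space A concept store from [make_toy_concept_space()] (any store
#'   with a `"cluster"` attribute works).
#' @param subject_id,condition,category_label Transcript metadata.
#' @param seed Overrides `profile$seed`.
#' @return A [transcript()] with attributes `"planted_switches"` (positions
#'   in 2..N where the emitting cluster changed) and `"planted_clusters"`
#'   (per-token cluster id, `NA` for repeats of earlier words).
#' @export
simulate_transcript <- function(profile, space, subject_id = "sim",
                                condition = "semantic",
                                category_label = "toy",
                                seed = profile$seed) {
  stopifnot(inherits(profile, "cvf_sim_profile"),
            inherits(space, "cvf_concept_store"))
  labels <- attr(space, "cluster")
  if (is.null(labels))
    stop("`space` lacks planted cluster labels", call. = FALSE)
  with_seed(seed, {
    pool <- split(names(labels), labels)
    pick <- function(words) {
      if (profile$typicality_bias == 0 || length(words) == 1L)
        return(sample(words, 1L))
      # preserve generation order as a typicality rank (1 = most typical)
      w <- seq_along(words)^(-profile$typicality_bias)
      sample(words, 1L, prob = w)
    }
    tokens <- character(0)
    clusters <- integer(0)
    cur <- sample(names(pool), 1L)
    n_distinct <- 0L
    truncated <- FALSE
    while (n_distinct < profile$n_words) {
      if (length(pool[[cur]]) == 0L ||
          (n_distinct > 0L &&
           stats::runif(1) < profile$cluster_switch_prob)) {
        avail <- names(pool)[vapply(pool, length, integer(1)) > 0L &
                               names(pool) != cur]
        if (length(avail) == 0L) {
          if (length(pool[[cur]]) == 0L) { truncated <- TRUE; break }
        } else cur <- if (length(avail) == 1L) avail else sample(avail, 1L)
      }
      w <- pick(pool[[cur]])
      pool[[cur]] <- setdiff(pool[[cur]], w)
      tokens <- c(tokens, w)
      clusters <- c(clusters, as.integer(cur))
      n_distinct <- n_distinct + 1L
      if (length(tokens) > 0L && stats::runif(1) < profile$repeat_prob) {
        tokens <- c(tokens, sample(tokens, 1L))
        clusters <- c(clusters, NA_integer_)
      }
    }
    if (truncated)
      warning("lexicon exhausted: transcript truncated to ",
              length(tokens), " tokens", call. = FALSE)
    onsets <- sample_onsets(length(tokens), profile$duration_s,
                            profile$rate_decay)
    t <- transcript(subject_id, condition, category_label, tokens, onsets,
                    duration_s = profile$duration_s, age = profile$age,
                    education = profile$education,
                    computer_use = profile$computer_use)
    filled <- clusters
    for (i in seq_along(filled))  # repeats inherit the running cluster
      if (is.na(filled[i]) && i > 1L) filled[i] <- filled[i - 1L]
    attr(t, "planted_clusters") <- clusters
    attr(t, "planted_switches") <-
      which(diff(filled) != 0L) + 1L
    t
  })
}

#' Simulate a control cohort with a known normative structure
#'
#' Draws demographics per subject, sets each subject's target correct-word
#' count from the linear model `cw = intercept + coef_education * education
#' + coef_computer_use * computer_use + N(0, noise_sd)` (rounded, floored
#' at 3), and simulates a transcript with exactly that many distinct words,
#' so [fit_norms()] on the scored cohort recovers the planted coefficients.
#'
#' @param n_subjects Number of subjects.
#' @param space Concept space for [simulate_transcript()].
#' @param profile Base [sim_profile()]; `n_words`, demographics and `seed`
#'   are overridden per subject.
#' @param cw_model List: `intercept`, `coef_education`,
#'   `coef_computer_use`, `noise_sd`.
#' @param education_mean,education_sd,computer_use_mean,computer_use_sd,age_mean,age_sd
#'   Demographic sampling distributions (computer use is rounded and
#'   clamped to the 1--8 Likert range; age clamped to 18--82).
#' @param seed Integer seed fixing the whole cohort.
#' @return List with `transcripts` (list of [transcript()]) and `truth`
#'   (data frame: `subject_id`, `age`, `education`, `computer_use`, `cw`).
#' @export
simulate_cohort <- function(n_subjects, space, profile = sim_profile(),
                            cw_model = list(intercept = 10,
                                            coef_education = 0.8,
                                            coef_computer_use = 0.9,
                                            noise_sd = 2),
                            education_mean = 14.5, education_sd = 2,
                            computer_use_mean = 5.1, computer_use_sd = 1.9,
                            age_mean = 40, age_sd = 21, seed = 1) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    edu <- stats::rnorm(n_subjects, education_mean, education_sd)
    cuse <- pmin(8, pmax(1, round(stats::rnorm(n_subjects,
                                               computer_use_mean,
                                               computer_use_sd))))
    age <- pmin(82, pmax(18, round(stats::rnorm(n_subjects, age_mean,
                                                age_sd))))
    cw <- pmax(3, round(cw_model$intercept +
                          cw_model$coef_education * edu +
                          cw_model$coef_computer_use * cuse +
                          stats::rnorm(n_subjects, 0, cw_model$noise_sd)))
    seeds <- sample.int(.Machine$integer.max, n_subjects)
    transcripts <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      p <- profile
      p$n_words <- cw[i]
      p$age <- age[i]; p$education <- edu[i]; p$computer_use <- cuse[i]
      transcripts[[i]] <- simulate_transcript(
        p, space, subject_id = sprintf("sim%04d", i), seed = seeds[i])
    }
    list(transcripts = transcripts,
         truth = data.frame(
           subject_id = sprintf("sim%04d", seq_len(n_subjects)),
           age = age, education = edu, computer_use = cuse, cw = cw))
  })
}
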