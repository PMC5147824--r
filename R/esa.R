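#' Sparse concept-vector store
#'
#' Maps tokens to sparse non-negative concept vectors (named numeric
#' vectors: concept id -> weight), the substrate for all cosine-based
#' semantic measures.  An optional precomputed pairwise-cosine cache can
#' stand in for (or override) vector arithmetic, for compatibility with
#' exported word-pair association databases.
#'
#' @param vectors Named list: token -> named numeric vector of non-negative
#'   concept weights, each with at least one positive entry.
#' @param cosine_cache Optional data frame (token_a, token_b, cosine) of
#'   precomputed pairwise cosines (symmetric lookup).
#' @return An object of class `cvf_concept_store`.
#' @export
concept_store <- function(vectors = list(), cosine_cache = NULL) {
  if (length(vectors)) {
    if (is.null(names(vectors)) || any(!nzchar(names(vectors))))
      stop("every vector must be named by its token", call. = FALSE)
    ok <- vapply(vectors, function(v) {
      is.numeric(v) && length(v) > 0 && !is.null(names(v)) &&
        all(v >= 0) && any(v > 0)
    }, logical(1))
    if (!all(ok))
      stop("invalid concept vector(s) for: ",
           paste(names(vectors)[!ok], collapse = ", "), call. = FALSE)
  }
  cache <- NULL
  if (!is.null(cosine_cache)) {
    stopifnot(is.data.frame(cosine_cache), ncol(cosine_cache) >= 3)
    a <- as.character(cosine_cache[[1]])
    b <- as.character(cosine_cache[[2]])
    val <- as.numeric(cosine_cache[[3]])
    cache <- c(stats::setNames(val, paste(a, b, sep = "\r")),
               stats::setNames(val, paste(b, a, sep = "\r")))
  }
  structure(list(vectors = vectors, cosine_cache = cache),
            class = "cvf_concept_store")
}

#' Read a concept store from three-column TSV (token, concept_id, weight)
#'
#' @param path Path to the TSV file (header expected).
#' @return A [concept_store()].
#' @export
read_concept_store <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop(sprintf("%s: expected columns token, concept_id, weight", path),
         call. = FALSE)
  tok <- normalize_token(as.character(df[[1]]))
  vecs <- lapply(split(seq_len(nrow(df)), tok), function(i)
    stats::setNames(as.numeric(df[[3]][i]), as.character(df[[2]][i])))
  concept_store(vecs)
}

#' Read a pairwise-cosine cache TSV (token_a, token_b, cosine)
#'
#' @param path Path to the TSV file (header expected).
#' @return A [concept_store()] backed only by the cache.
#' @export
read_cosine_cache <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop(sprintf("%s: expected columns token_a, token_b, cosine", path),
         call. = FALSE)
  df[[1]] <- normalize_token(as.character(df[[1]]))
  df[[2]] <- normalize_token(as.character(df[[2]]))
  concept_store(cosine_cache = df)
}

#' Cosine similarity between sparse concept vectors
#'
#' `dot(u, v) / (|u| |v|)` over the shared support.  With non-negative
#' weights the result lies in [0, 1].
#'
#' @param u,v Named numeric vectors (concept id -> weight).
#' @return Cosine similarity in [0, 1].
#' @examples
#' cosine(c(x = 1, y = 1), c(x = 1))  # 0.7071
#' @export
cosine <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine undefined for a zero vector", call. = FALSE)
  shared <- intersect(names(u), names(v))
  if (length(shared) == 0L) return(0)
  min(1, sum(u[shared] * v[shared]) / (nu * nv))
}

store_tokens <- function(store) {
  tok <- names(store$vectors)
  if (!is.null(store$cosine_cache))
    tok <- union(tok, unique(sub("\r.*$", "", names(store$cosine_cache))))
  tok
}

store_cosine <- function(store, a, b) {
  if (a == b) return(1)
  if (!is.null(store$cosine_cache)) {
    hit <- store$cosine_cache[paste(a, b, sep = "\r")]
    if (!is.na(hit)) return(unname(hit))
  }
  if (is.null(store$vectors[[a]]) || is.null(store$vectors[[b]]))
    stop(sprintf("no cosine available for pair ('%s', '%s')", a, b),
         call. = FALSE)
  cosine(store$vectors[[a]], store$vectors[[b]])
}

#' Resolve transcript tokens against a concept store
#'
#' Tokens missing from the store are dropped from semantic computations
#' (with a warning); the coverage fraction is reported so downstream
#' summaries can flag incomplete resolution.
#'
#' @param tokens Character vector of normalized tokens.
#' @param store A [concept_store()].
#' @return List with `tokens` (the resolvable subsequence, order kept) and
#'   `coverage` (resolved fraction; `NaN` for empty input).
#' @export
resolve_tokens <- function(tokens, store) {
  stopifnot(inherits(store, "cvf_concept_store"))
  known <- tokens %in% store_tokens(store)
  if (any(!known))
    warning("dropping token(s) missing from concept store: ",
            paste(unique(tokens[!known]), collapse = ", "), call. = FALSE)
  list(tokens = tokens[known], coverage = mean(known))
}

#' Pairwise (adjacent) cosine series
#'
#' Cosines between each successive token pair, the basis of the PW-ESA
#' mean.  Adjacent identical tokens (immediate repetitions) give 1.
#'
#' @param tokens Character vector of tokens, all resolvable in `store`
#'   (see [resolve_tokens()]).
#' @param store A [concept_store()].
#' @return Numeric vector of length N - 1.
#' @export
pw_esa_series <- function(tokens, store) {
  stopifnot(inherits(store, "cvf_concept_store"))
  n <- length(tokens)
  if (n < 2L)
    stop("pairwise similarity needs at least two resolvable tokens",
         call. = FALSE)
  vapply(seq_len(n - 1L), function(i)
    store_cosine(store, tokens[i], tokens[i + 1L]), numeric(1))
}

#' Mean adjacent-pair cosine (PW-ESA)
#'
#' @inheritParams pw_esa_series
#' @return Mean of [pw_esa_series()], in [0, 1].
#' @export
pw_esa <- function(tokens, store) mean(pw_esa_series(tokens, store))

#' Mean all-pair cosine (A-ESA)
#'
#' Mean cosine over all unordered distinct-position pairs: the expected
#' adjacent similarity if the same words were produced in random order.
#' Repeated tokens are kept as separate positions by default, so cross-
#' position self-pairs contribute 1; set `distinct_types = TRUE` to
#' collapse repeats to word types first.
#'
#' @inheritParams pw_esa_series
#' @param distinct_types Collapse repeated tokens to types before pairing.
#' @return Mean pairwise cosine in [0, 1].
#' @export
a_esa <- function(tokens, store, distinct_types = FALSE) {
  stopifnot(inherits(store, "cvf_concept_store"))
  if (distinct_types) tokens <- unique(tokens)
  n <- length(tokens)
  if (n < 2L)
    stop("all-pair similarity needs at least two resolvable tokens",
         call. = FALSE)
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      total <- total + store_cosine(store, tokens[i], tokens[j])
  total / (n * (n - 1L) / 2)
}

#' Semantic organization index (SOI)
#'
#' The PW-ESA / A-ESA ratio.  Values above 1 indicate that successive
#' words are more related than a random ordering of the same words, i.e.
#' semantically organized retrieval.
#'
#' @inheritParams a_esa
#' @return SOI (non-negative real).
#' @export
soi <- function(tokens, store, distinct_types = FALSE) {
  a <- a_esa(tokens, store, distinct_types)
  if (a == 0)
    stop("SOI undefined: all-pair mean cosine is zero", call. = FALSE)
  pw_esa(tokens, store) / a
}

#' Detect semantic switches from the cosine series
#'
#' A switch occurs before token i+1 when the adjacent cosine
#' `cos(token_i, token_{i+1})` falls strictly below `threshold_fraction`
#' times the transcript's A-ESA.  The default fraction 0.75 matches the
#' operating point at which threshold-based switch counts align with
#' subcategory-based (Troyer) counts.
#'
#' @inheritParams a_esa
#' @param threshold_fraction Positive fraction of the A-ESA used as the
#'   switch threshold (sweepable, e.g. 1.00 / 0.75 / 0.50).
#' @return Integer vector of switch positions: indices (2..N) of tokens
#'   that start a new cluster.
#' @export
detect_switches <- function(tokens, store, threshold_fraction = 0.75,
                            distinct_types = FALSE) {
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0)
    stop("`threshold_fraction` must be positive", call. = FALSE)
  thr <- threshold_fraction * a_esa(tokens, store, distinct_types)
  series <- pw_esa_series(tokens, store)
  which(series < thr) + 1L
}

#' Cluster statistics from switch positions
#'
#' Clusters are maximal runs of consecutive tokens with no internal switch;
#' their sizes always partition N and `n_clusters = n_switches + 1`.
#' Multi-word clusters have size >= 2; their mean size is averaged over
#' multi-word clusters only (0 when there are none).
#'
#' @param n_tokens Number of tokens in the sequence.
#' @param switch_positions Integer vector of switch positions (indices in
#'   2..N of cluster-starting tokens), as from [detect_switches()] or
#'   [troyer_switches()].
#' @return List: `n_clusters`, `cluster_sizes`, `n_multiword_clusters`,
#'   `mean_multiword_cluster_size`.
#' @export
cluster_stats <- function(n_tokens, switch_positions) {
  if (n_tokens == 0L)
    return(list(n_clusters = 0L, cluster_sizes = integer(0),
                n_multiword_clusters = 0L, mean_multiword_cluster_size = 0))
  sp <- sort(unique(as.integer(switch_positions)))
  if (length(sp) && (min(sp) < 2L || max(sp) > n_tokens))
    stop("switch positions must lie in 2..n_tokens", call. = FALSE)
  sizes <- diff(c(1L, sp, n_tokens + 1L))
  multi <- sizes[sizes >= 2L]
  list(
    n_clusters = length(sizes),
    cluster_sizes = sizes,
    n_multiword_clusters = length(multi),
    mean_multiword_cluster_size = if (length(multi)) mean(multi) else 0
  )
}

#' Concept-vector semantic summary of a token sequence
#'
#' Computes PW-ESA, A-ESA, SOI, switch positions at the given threshold
#' fraction, and multi-word cluster statistics, after resolving tokens
#' against the store.
#'
#' @param tokens Character vector of tokens (repetitions retained).
#' @param store A [concept_store()].
#' @param threshold_fraction Switch threshold as a fraction of A-ESA.
#' @param distinct_types Passed to [a_esa()].
#' @return A list of class `cvf_esa_summary`: `pw_esa`, `a_esa`, `soi`,
#'   `switch_positions`, `n_switches`, `n_multiword_clusters`,
#'   `mean_multiword_cluster_size`, `cluster_sizes`, `coverage`,
#'   `n_resolved`.
#' @export
esa_summary <- function(tokens, store, threshold_fraction = 0.75,
                        distinct_types = FALSE) {
  res <- resolve_tokens(tokens, store)
  tok <- res$tokens
  if (length(tok) < 2L)
    stop("semantic summary needs at least two resolvable tokens",
         call. = FALSE)
  a <- a_esa(tok, store, distinct_types)
  series <- pw_esa_series(tok, store)
  sw <- which(series < threshold_fraction * a) + 1L
  cs <- cluster_stats(length(tok), sw)
  structure(list(
    pw_esa = mean(series),
    a_esa = a,
    soi = if (a > 0) mean(series) / a else NA_real_,
    switch_positions = sw,
    n_switches = length(sw),
    n_multiword_clusters = cs$n_multiword_clusters,
    mean_multiword_cluster_size = cs$mean_multiword_cluster_size,
    cluster_sizes = cs$cluster_sizes,
    coverage = res$coverage,
    n_resolved = length(tok)
  ), class = "cvf_esa_summary")
}
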