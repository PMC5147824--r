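#' Word-frequency table
#'
#' Wraps a token -> corpus-count mapping (counts >= 1), e.g. counts drawn
#' from a large reference corpus such as the American National Corpus.
#'
#' @param counts Named numeric vector of corpus counts.
#' @param source_label Free-text provenance label.
#' @return An object of class `cvf_frequency_table`.
#' @export
frequency_table <- function(counts, source_label = "unspecified") {
  if (length(counts) == 0L)
    stop("frequency table is empty", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all counts must be named by token", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("all corpus counts must be finite and >= 1", call. = FALSE)
  structure(list(counts = counts, source_label = source_label),
            class = "cvf_frequency_table")
}

#' Read a frequency table from two-column TSV (token, count)
#'
#' @param path Path to the TSV file; a header line is expected.
#' @param source_label Provenance label (defaults to the file name).
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path, source_label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("%s: expected columns token, count", path), call. = FALSE)
  counts <- as.numeric(df[[2]])
  names(counts) <- normalize_token(as.character(df[[1]]))
  frequency_table(counts, source_label)
}

#' Log10 word frequency
#'
#' Returns `log10(count)` for tokens present in the table.  Unknown tokens
#' are imputed with the log10 of the table's minimum count, keeping means
#' finite for rare or novel words.
#'
#' @param token Character vector of normalized tokens.
#' @param table A [frequency_table()].
#' @return Numeric vector of log10 frequencies.
#' @examples
#' tab <- frequency_table(c(dog = 1000, axolotl = 2))
#' log_word_frequency(c("dog", "unknown-word"), tab)
#' @export
log_word_frequency <- function(token, table) {
  stopifnot(inherits(table, "cvf_frequency_table"))
  cnt <- table$counts[token]
  cnt[is.na(cnt)] <- min(table$counts)
  unname(log10(cnt))
}

#' Count syllables in a token
#'
#' Dictionary lookup when a pronunciation lexicon is supplied; otherwise a
#' deterministic orthographic heuristic: count maximal vowel groups
#' (aeiouy), subtract one for a terminal consonant + "e", floor at one.
#' Hyphenated compounds are scored per part and summed.
#'
#' @param token Character vector of normalized tokens.
#' @param lexicon Optional named integer vector token -> syllable count;
#'   consulted (whole token, then per part) before the heuristic.
#' @return Integer vector of syllable counts (>= 1 per alphabetic part).
#' @examples
#' count_syllables(c("cat", "elephant", "horse", "red-fox"))
#' @export
count_syllables <- function(token, lexicon = NULL) {
  one_part <- function(w) {
    if (!is.null(lexicon) && w %in% names(lexicon))
      return(as.integer(lexicon[[w]]))
    if (!grepl("[a-z]", w))
      stop(sprintf("token part '%s' has no alphabetic characters", w),
           call. = FALSE)
    groups <- gregexpr("[aeiouy]+", w)[[1]]
    n <- if (groups[1] == -1L) 0L else length(groups)
    # silent terminal e: consonant + "e" at word end drops one group
    if (n > 1L && grepl("[^aeiouy]e$", w)) n <- n - 1L
    max(1L, n)
  }
  vapply(token, function(w) {
    if (!is.null(lexicon) && w %in% names(lexicon))
      return(as.integer(lexicon[[w]]))
    sum(vapply(strsplit(w, "-", fixed = TRUE)[[1]], one_part, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a cohort typicality table
#'
#' Counts, for each token, the number of cohort subjects who produced it at
#' least once; repetitions within a subject do not inflate counts.  All
#' transcripts must share one category.
#'
#' @param cohort List of [transcript()] objects.
#' @return An object of class `cvf_typicality_table`: `counts` (named
#'   integer vector) and `n_subjects`.
#' @export
build_typicality_table <- function(cohort) {
  if (length(cohort) == 0L)
    stop("cohort is empty", call. = FALSE)
  stopifnot(all(vapply(cohort, inherits, logical(1), "cvf_transcript")))
  cats <- unique(vapply(cohort, `[[`, character(1), "category_label"))
  if (length(cats) > 1L)
    stop("cohort mixes categories: ", paste(cats, collapse = ", "),
         call. = FALSE)
  per_subject <- lapply(cohort, function(t) unique(t$events$token))
  tab <- table(unlist(per_subject))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, n_subjects = length(cohort)),
            class = "cvf_typicality_table")
}

#' Read / write a typicality table
#'
#' TSV with a `# n_subjects: N` header line followed by token /
#' producer_count columns.
#'
#' @param path File path.
#' @return [read_typicality_table()] returns a `cvf_typicality_table`;
#'   `write_typicality_table()` returns `path` invisibly.
#' @export
read_typicality_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*n_subjects:", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop(sprintf("%s: missing '# n_subjects: N' header", path), call. = FALSE)
  n_subjects <- as.integer(sub("^#\\s*n_subjects:\\s*", "", hdr))
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                          stringsAsFactors = FALSE)
  counts <- as.integer(df[[2]])
  names(counts) <- normalize_token(as.character(df[[1]]))
  if (any(counts < 1L) || any(counts > n_subjects))
    stop(sprintf("%s: producer counts outside 1..n_subjects", path),
         call. = FALSE)
  structure(list(counts = counts, n_subjects = n_subjects),
            class = "cvf_typicality_table")
}

#' @rdname read_typicality_table
#' @param table A `cvf_typicality_table`.
#' @export
write_typicality_table <- function(table, path) {
  stopifnot(inherits(table, "cvf_typicality_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_subjects: %d", table$n_subjects), con)
  utils::write.table(
    data.frame(token = names(table$counts), producer_count = table$counts),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort typicality of a transcript, as a percentage
#'
#' The median producer count over the transcript's words, divided by the
#' cohort size, times 100.  Tokens absent from the table count as produced
#' by one subject (the subject under analysis).  Medians over even-length
#' lists are the mean of the central pair.
#'
#' @param t A [transcript()] or a character vector of tokens.
#' @param table A `cvf_typicality_table`.
#' @return Typicality percentage in (0, 100].
#' @export
typicality_percent <- function(t, table) {
  stopifnot(inherits(table, "cvf_typicality_table"))
  tok <- if (inherits(t, "cvf_transcript")) t$events$token else t
  if (length(tok) == 0L)
    stop("typicality undefined for an empty transcript", call. = FALSE)
  cnt <- table$counts[tok]
  cnt[is.na(cnt)] <- 1L
  100 * stats::median(cnt) / table$n_subjects
}

#' Lexical summary of a transcript
#'
#' Mean log10 word frequency, mean syllable count, and cohort typicality.
#' By default every scored-in-window word (including repetitions and
#' out-of-category words) enters the means.
#'
#' @param t A [transcript()].
#' @param freq_table Optional [frequency_table()]; `mean_lwf` is `NA`
#'   without one.
#' @param typ_table Optional `cvf_typicality_table`; typicality is `NA`
#'   without one.
#' @param syllable_lexicon Optional lookup for [count_syllables()].
#' @param window_s Scoring window (half-open), defaults to full duration.
#' @param correct_only If `TRUE`, restrict to correct words under `rule`.
#' @param rule Required when `correct_only = TRUE`.
#' @return A list of class `cvf_lexical_summary`: `mean_lwf`,
#'   `mean_syllables`, `typicality_pct`, `n_words`.
#' @export
lexical_summary <- function(t, freq_table = NULL, typ_table = NULL,
                            syllable_lexicon = NULL,
                            window_s = t$duration_s,
                            correct_only = FALSE, rule = NULL) {
  stopifnot(inherits(t, "cvf_transcript"))
  tok <- t$events$token[t$events$onset_s < window_s]
  if (correct_only) {
    if (is.null(rule))
      stop("`correct_only = TRUE` requires `rule`", call. = FALSE)
    keep <- classify_membership(tok, rule) & !detect_repetitions(tok)
    tok <- tok[keep]
  }
  if (length(tok) == 0L) {
    return(structure(list(mean_lwf = NA_real_, mean_syllables = NA_real_,
                          typicality_pct = NA_real_, n_words = 0L),
                     class = "cvf_lexical_summary"))
  }
  structure(list(
    mean_lwf = if (is.null(freq_table)) NA_real_
               else mean(log_word_frequency(tok, freq_table)),
    mean_syllables = mean(count_syllables(tok, syllable_lexicon)),
    typicality_pct = if (is.null(typ_table)) NA_real_
                     else typicality_percent(tok, typ_table),
    n_words = length(tok)
  ), class = "cvf_lexical_summary")
}
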