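#' Normalize a raw word token
#'
#' Lowercases, strips surrounding whitespace, and joins internal whitespace
#' runs with a single hyphen, so multi-word responses ("red fox") become
#' single hyphenated tokens ("red-fox").  The function is idempotent.
#'
#' @param raw Character vector of raw responses.
#' @return Character vector of normalized tokens.
#' @examples
#' normalize_token(c(" Dog ", "red fox"))
#' @export
normalize_token <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be character", call. = FALSE)
  x <- tolower(trimws(raw))
  x <- gsub("[[:space:]]+", "-", x)
  bad <- !nzchar(x)
  if (any(bad)) {
    stop("token(s) empty after normalization at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  x
}

#' Flag repeated tokens
#'
#' A position is flagged as a repetition when its token exactly matches any
#' earlier token in the sequence; first occurrences are never flagged.
#' Morphological variants ("dog"/"dogs") are distinct tokens unless a
#' `variant_map` collapses them.
#'
#' @param tokens Character vector of normalized tokens.
#' @param variant_map Optional named character vector mapping variant
#'   spellings to a canonical form before comparison (off by default).
#' @return Logical vector, `TRUE` where the token repeats an earlier one.
#' @examples
#' detect_repetitions(c("dog", "cat", "dog"))
#' @export
detect_repetitions <- function(tokens, variant_map = NULL) {
  if (length(tokens) == 0L) return(logical(0))
  key <- tokens
  if (!is.null(variant_map)) {
    hit <- key %in% names(variant_map)
    key[hit] <- unname(variant_map[key[hit]])
  }
  duplicated(key)
}

#' Define a category acceptance rule
#'
#' Semantic conditions accept tokens from a fixed lexicon; phonemic
#' conditions accept tokens starting with a given letter.  Tokens on the
#' exclusion list (proper nouns, derivatives) are rejected in either mode.
#'
#' @param kind `"lexicon"` (semantic) or `"initial_letter"` (phonemic).
#' @param lexicon Character vector of accepted tokens (lexicon rules).
#' @param letter Single character (initial-letter rules).
#' @param exclusions Character vector of disallowed tokens.
#' @return An object of class `cvf_category_rule`.
#' @export
category_rule <- function(kind = c("lexicon", "initial_letter"),
                          lexicon = NULL, letter = NULL,
                          exclusions = character()) {
  kind <- match.arg(kind)
  if (kind == "lexicon") {
    if (is.null(lexicon) || length(lexicon) == 0L)
      stop("lexicon rule requires a non-empty `lexicon`", call. = FALSE)
    if (!is.null(letter))
      stop("lexicon rule must not set `letter`", call. = FALSE)
    lexicon <- normalize_token(lexicon)
  } else {
    if (is.null(letter) || nchar(letter) != 1L)
      stop("initial_letter rule requires a single-character `letter`",
           call. = FALSE)
    if (!is.null(lexicon))
      stop("initial_letter rule must not set `lexicon`", call. = FALSE)
    letter <- tolower(letter)
  }
  if (length(exclusions)) exclusions <- normalize_token(exclusions)
  structure(list(kind = kind, lexicon = lexicon, letter = letter,
                 exclusions = exclusions),
            class = "cvf_category_rule")
}

#' Classify a token as in or out of category
#'
#' @param token Character vector of normalized tokens.
#' @param rule A [category_rule()].
#' @return Logical vector, `TRUE` for in-category tokens.  Exclusions take
#'   precedence over membership.
#' @examples
#' rule <- category_rule("initial_letter", letter = "F")
#' classify_membership(c("fish", "truck"), rule)
#' @export
classify_membership <- function(token, rule) {
  stopifnot(inherits(rule, "cvf_category_rule"))
  if (rule$kind == "lexicon") {
    ok <- token %in% rule$lexicon
  } else {
    ok <- tolower(substr(token, 1L, 1L)) == rule$letter
  }
  ok & !(token %in% rule$exclusions)
}

#' Construct a fluency transcript
#'
#' One subject in one condition: ordered timestamped tokens plus the
#' demographics used by the normative model.
#'
#' @param subject_id Opaque subject identifier.
#' @param condition `"semantic"` or `"phonemic"`.
#' @param category_label Category name ("animals") or letter ("F").
#' @param tokens Character vector of responses (normalized on input).
#' @param onsets_s Numeric vector of word onsets in seconds from test start.
#' @param duration_s Test duration in seconds (default 90).
#' @param age,education,computer_use Demographics: age in years, education
#'   in years, daily computer use on a 1--8 Likert scale.
#' @param allow_unsorted If `TRUE`, out-of-order onsets are re-sorted
#'   (stable); otherwise they are an error.
#' @return An object of class `cvf_transcript` with an `events` data frame
#'   (`token`, `onset_s`) sorted by onset (ties keep input order).
#' @export
transcript <- function(subject_id, condition = c("semantic", "phonemic"),
                       category_label, tokens, onsets_s, duration_s = 90,
                       age = NA_real_, education = NA_real_,
                       computer_use = NA_real_, allow_unsorted = FALSE) {
  condition <- match.arg(condition)
  if (length(tokens) != length(onsets_s))
    stop("`tokens` and `onsets_s` must have equal length", call. = FALSE)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a positive number", call. = FALSE)
  if (length(onsets_s)) {
    if (any(!is.finite(onsets_s)) || any(onsets_s < 0))
      stop("onsets must be finite and non-negative", call. = FALSE)
    if (any(onsets_s > duration_s))
      stop("onset beyond test duration", call. = FALSE)
    if (is.unsorted(onsets_s)) {
      if (!allow_unsorted)
        stop("onsets are not sorted; use `allow_unsorted = TRUE` to resort",
             call. = FALSE)
      ord <- order(onsets_s)  # stable: ties keep input order
      tokens <- tokens[ord]
      onsets_s <- onsets_s[ord]
    }
    tokens <- normalize_token(tokens)
  } else {
    tokens <- character(0)
    onsets_s <- numeric(0)
  }
  structure(list(
    subject_id = as.character(subject_id),
    condition = condition,
    category_label = as.character(category_label),
    duration_s = duration_s,
    events = data.frame(token = tokens, onset_s = onsets_s,
                        stringsAsFactors = FALSE),
    demographics = list(age = age, education = education,
                        computer_use = computer_use)
  ), class = "cvf_transcript")
}

#' @export
print.cvf_transcript <- function(x, ...) {
  cat(sprintf("<cvf_transcript> %s | %s (%s) | %d words in %.0f s\n",
              x$subject_id, x$condition, x$category_label,
              nrow(x$events), x$duration_s))
  invisible(x)
}

#' Score a transcript
#'
#' Counts total, correct, repeated and out-of-category words among events
#' with onset strictly before `window_s` (half-open window, so a word begun
#' at exactly 60.0 s lies outside a 60-s window).  The correct-word score is
#' total minus repetitions and out-of-category words; a word that is both
#' repeated and out of category is counted once, as out-of-category, so the
#' three classes always partition the total.
#'
#' @param t A [transcript()].
#' @param rule A [category_rule()].
#' @param window_s Scoring window in seconds; defaults to the full test.
#' @param variant_map Passed to [detect_repetitions()].
#' @return A list of class `cvf_score_summary`: `total`, `correct`,
#'   `repeats`, `out_of_category`, `pct_repeats` (0 when no words).
#' @examples
#' rule <- category_rule("lexicon", lexicon = c("dog", "cat"))
#' tr <- transcript("s1", "semantic", "animals",
#'                  c("dog", "cat", "dog", "truck"), c(2, 5, 9, 14))
#' score_transcript(tr, rule)
#' @export
score_transcript <- function(t, rule, window_s = t$duration_s,
                             variant_map = NULL) {
  stopifnot(inherits(t, "cvf_transcript"))
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0)
    stop("`window_s` must be a positive number", call. = FALSE)
  if (window_s > t$duration_s)
    stop("`window_s` exceeds test duration", call. = FALSE)
  tok <- t$events$token[t$events$onset_s < window_s]
  total <- length(tok)
  rep_flag <- detect_repetitions(tok, variant_map)
  out_flag <- !classify_membership(tok, rule)
  out_of_category <- sum(out_flag)
  repeats <- sum(rep_flag & !out_flag)
  structure(list(
    total = total,
    correct = total - repeats - out_of_category,
    repeats = repeats,
    out_of_category = out_of_category,
    pct_repeats = if (total == 0L) 0 else 100 * repeats / total
  ), class = "cvf_score_summary")
}

#' @export
print.cvf_score_summary <- function(x, ...) {
  cat(sprintf(
    "<cvf_score_summary> total %d | correct %d | repeats %d (%.1f%%) | out-of-category %d\n",
    x$total, x$correct, x$repeats, x$pct_repeats, x$out_of_category))
  invisible(x)
}
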