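#' Read a transcript from CSV
#'
#' Expected columns: `subject_id`, `condition`, `category`, `duration_s`,
#' `token`, `onset_s`.  Subject-level columns must be constant within the
#' file; one file holds one subject in one condition.
#'
#' @param path Path to the CSV file.
#' @param age,education,computer_use Demographics, if not carried as
#'   (constant) optional columns of the same names.
#' @param allow_unsorted Re-sort out-of-order onsets instead of erroring.
#' @return A [transcript()].
#' @export
read_transcript_csv <- function(path, age = NA_real_, education = NA_real_,
                                computer_use = NA_real_,
                                allow_unsorted = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "category", "duration_s",
            "token", "onset_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in c("subject_id", "condition", "category", "duration_s")) {
    if (length(unique(df[[col]])) > 1L)
      stop(sprintf("%s: column '%s' is not constant", path, col),
           call. = FALSE)
  }
  if (!is.numeric(df$onset_s))
    stop(sprintf("%s: non-numeric onset_s (first offending line: %d)",
                 path, which(is.na(suppressWarnings(
                   as.numeric(df$onset_s))))[1] + 1L), call. = FALSE)
  demo <- function(col, given) {
    if (!is.na(given)) given
    else if (col %in% names(df)) df[[col]][1] else NA_real_
  }
  transcript(
    subject_id = df$subject_id[1],
    condition = df$condition[1],
    category_label = df$category[1],
    tokens = df$token,
    onsets_s = df$onset_s,
    duration_s = df$duration_s[1],
    age = demo("age", age),
    education = demo("education", education),
    computer_use = demo("computer_use", computer_use),
    allow_unsorted = allow_unsorted
  )
}

#' Write a transcript to CSV
#'
#' @param t A [transcript()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_csv <- function(t, path) {
  stopifnot(inherits(t, "cvf_transcript"))
  df <- data.frame(
    subject_id = t$subject_id, condition = t$condition,
    category = t$category_label, duration_s = t$duration_s,
    token = t$events$token, onset_s = t$events$onset_s,
    age = t$demographics$age, education = t$demographics$education,
    computer_use = t$demographics$computer_use,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transcript from a single-record JSON file
#'
#' Layout mirrors the in-memory object: scalar fields `subject_id`,
#' `condition`, `category`, `duration_s`, demographics, and parallel arrays
#' `tokens` / `onsets_s`.
#'
#' @inheritParams read_transcript_csv
#' @return A [transcript()].
#' @export
read_transcript_json <- function(path, allow_unsorted = FALSE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("subject_id", "condition", "category", "duration_s",
            "tokens", "onsets_s")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s: missing field(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  demo <- x$demographics %||% list()
  transcript(
    subject_id = x$subject_id, condition = x$condition,
    category_label = x$category, tokens = x$tokens,
    onsets_s = as.numeric(x$onsets_s), duration_s = x$duration_s,
    age = demo$age %||% NA_real_,
    education = demo$education %||% NA_real_,
    computer_use = demo$computer_use %||% NA_real_,
    allow_unsorted = allow_unsorted
  )
}

#' Write a transcript to a single-record JSON file
#'
#' @param t A [transcript()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_json <- function(t, path) {
  stopifnot(inherits(t, "cvf_transcript"))
  jsonlite::write_json(list(
    subject_id = t$subject_id, condition = t$condition,
    category = t$category_label, duration_s = t$duration_s,
    tokens = t$events$token, onsets_s = t$events$onset_s,
    demographics = t$demographics
  ), path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a one-token-per-line word list
#'
#' Used for category lexica and exclusion lists.  Blank lines and lines
#' starting with `#` are ignored; tokens are normalized.
#'
#' @param path Path to the text file.
#' @return Character vector of normalized tokens.
#' @export
read_token_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_token(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
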