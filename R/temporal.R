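#' Word counts per time bin
#'
#' Assigns each word to half-open bins `[k*w, (k+1)*w)`; the default 15-s
#' width yields six bins for a 90-s test.
#'
#' @param t A [transcript()].
#' @param bin_width_s Bin width in seconds; must divide the test duration.
#' @return Named integer vector of counts, one per bin, names giving the
#'   bin start times in seconds.
#' @examples
#' tr <- transcript("s1", "semantic", "animals",
#'                  c("a", "b", "c"), c(1, 44.9, 45))
#' bin_counts(tr)
#' @export
bin_counts <- function(t, bin_width_s = 15) {
  stopifnot(inherits(t, "cvf_transcript"))
  if (!is.numeric(bin_width_s) || bin_width_s <= 0)
    stop("`bin_width_s` must be positive", call. = FALSE)
  n_bins <- t$duration_s / bin_width_s
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("`bin_width_s` must divide the test duration", call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  idx <- pmin(floor(t$events$onset_s / bin_width_s), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  names(counts) <- format((seq_len(n_bins) - 1L) * bin_width_s)
  counts
}

#' Temporal decline percentage (TDP)
#'
#' The percentage of words produced during the first half of the test
#' (onset strictly before `duration_s / 2`) relative to total word
#' production.  Values near 50 indicate a flat production rate; larger
#' values indicate steeper decline.
#'
#' @param t A [transcript()].
#' @param correct_only If `TRUE`, restrict to correct words under `rule`.
#' @param rule Required when `correct_only = TRUE`.
#' @return TDP in percent.
#' @export
tdp <- function(t, correct_only = FALSE, rule = NULL) {
  stopifnot(inherits(t, "cvf_transcript"))
  onsets <- t$events$onset_s
  if (correct_only) {
    if (is.null(rule))
      stop("`correct_only = TRUE` requires `rule`", call. = FALSE)
    tok <- t$events$token
    keep <- classify_membership(tok, rule) & !detect_repetitions(tok)
    onsets <- onsets[keep]
  }
  if (length(onsets) == 0L)
    stop("TDP undefined for an empty transcript", call. = FALSE)
  100 * sum(onsets < t$duration_s / 2) / length(onsets)
}

#' Interword intervals
#'
#' Differences between successive word onsets; length N - 1, each >= 0 for
#' sorted transcripts (simultaneous onsets give 0).
#'
#' @param t A [transcript()].
#' @return Numeric vector of onset differences in seconds (empty with
#'   fewer than two events).
#' @export
interword_intervals <- function(t) {
  stopifnot(inherits(t, "cvf_transcript"))
  if (nrow(t$events) < 2L) return(numeric(0))
  diff(t$events$onset_s)
}

#' Temporal summary of a transcript
#'
#' @param t A [transcript()].
#' @param bin_width_s Bin width for [bin_counts()].
#' @param rule Optional [category_rule()]; when given, a correct-word TDP
#'   variant is reported alongside the all-word TDP.
#' @return A list of class `cvf_temporal_summary`: `bin_counts`, `tdp`
#'   (all scored words), `tdp_correct` (or `NA`), `interword_intervals_s`.
#' @export
temporal_summary <- function(t, bin_width_s = 15, rule = NULL) {
  structure(list(
    bin_counts = bin_counts(t, bin_width_s),
    tdp = tdp(t),
    tdp_correct = if (is.null(rule)) NA_real_
                  else tdp(t, correct_only = TRUE, rule = rule),
    interword_intervals_s = interword_intervals(t)
  ), class = "cvf_temporal_summary")
}
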