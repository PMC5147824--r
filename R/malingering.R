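#' Six-sign malingering profile
#'
#' Compares a semantic-condition report against the control distribution in
#' the norms model and raises six binary signs.  Five signs mark response
#' styles characteristic of feigned impairment — short words
#' (`low_syllables`), frequent words (`high_lwf`), typical words
#' (`high_typicality`), many repetitions (`high_repeats`), and a semantic
#' organization index inside the normal range (`soi_in_normal_range`, SOI
#' above mean - 1 SD) — and each adds one point.  The sixth,
#' `tdp_abnormal` (abnormally steep temporal decline), is characteristic of
#' genuinely impaired performance and subtracts one point, so the index
#' total ranges from -1 to 5.
#'
#' @param measures A list or one-row data frame with `mean_syllables`,
#'   `mean_lwf`, `typicality_pct`, `pct_repeats`, `tdp`, `soi` (a
#'   [fluency_report()] works: its fields are extracted).
#' @param norms A [norms_model()] with thresholds and SOI moments.
#' @param tail `"p10"` (default) or `"p05"`: which control-distribution
#'   tail the five threshold signs fire at.
#' @return A list of class `cvf_sign_profile`: the six logical signs and
#'   `mi_total`.
#' @export
sign_profile <- function(measures, norms = default_norms(), tail = "p10") {
  stopifnot(inherits(norms, "cvf_norms_model"))
  if (inherits(measures, "cvf_fluency_report")) {
    measures <- list(
      mean_syllables = measures$lexical$mean_syllables,
      mean_lwf = measures$lexical$mean_lwf,
      typicality_pct = measures$lexical$typicality_pct,
      pct_repeats = measures$score$pct_repeats,
      tdp = measures$temporal$tdp,
      soi = measures$esa$soi)
  }
  th <- norms$thresholds
  need <- c("mean_syllables", "mean_lwf", "typicality_pct", "pct_repeats",
            "tdp")
  miss <- setdiff(need, names(th))
  if (length(miss) || is.na(norms$soi_mean) || is.na(norms$soi_sd))
    stop("norms model lacks threshold entries for: ",
         paste(c(miss,
                 if (is.na(norms$soi_mean)) "soi"), collapse = ", "),
         call. = FALSE)
  cut <- function(m) th[[m]][[tail]]
  flags <- list(
    low_syllables = isTRUE(measures$mean_syllables <= cut("mean_syllables")),
    high_lwf = isTRUE(measures$mean_lwf >= cut("mean_lwf")),
    high_typicality = isTRUE(measures$typicality_pct >=
                               cut("typicality_pct")),
    high_repeats = isTRUE(measures$pct_repeats >= cut("pct_repeats")),
    tdp_abnormal = isTRUE(measures$tdp >= cut("tdp")),
    soi_in_normal_range = isTRUE(measures$soi >
                                   norms$soi_mean - norms$soi_sd))
  flags$mi_total <- mi_total(flags)
  structure(flags, class = "cvf_sign_profile")
}

#' Malingering-index total from sign flags
#'
#' `+1` for each of the five malingering-style signs, `-1` when the
#' temporal decline is abnormal; range -1 to 5.
#'
#' @param flags List (or `cvf_sign_profile`) with logical elements
#'   `low_syllables`, `high_lwf`, `high_typicality`, `high_repeats`,
#'   `tdp_abnormal`, `soi_in_normal_range`.
#' @return Integer index total.
#' @export
mi_total <- function(flags) {
  plus <- c("low_syllables", "high_lwf", "high_typicality", "high_repeats",
            "soi_in_normal_range")
  sum(vapply(flags[plus], isTRUE, logical(1))) -
    as.integer(isTRUE(flags$tdp_abnormal))
}

#' Classify a malingering-index total
#'
#' @param mi Integer vector of index totals.
#' @param cutoff Flag subjects with `mi >= cutoff` (default 3 of 6 signs).
#' @return Logical vector: `TRUE` = flagged as probable malingering.
#' @export
classify_malingering <- function(mi, cutoff = 3L) {
  if (length(cutoff) != 1L || cutoff != round(cutoff))
    stop("`cutoff` must be a single integer", call. = FALSE)
  mi >= cutoff
}

#' Sensitivity and specificity of a cutoff classifier
#'
#' Applies `value >= cutoff` (or `<=` for deficit-direction scores such as
#' z-scores) and evaluates it against known group labels.
#'
#' @param values Numeric vector of scores (e.g. MI totals or z-scores).
#' @param is_malingerer Logical vector: `TRUE` for the target (malingering)
#'   class.
#' @param cutoff Decision threshold.
#' @param flag_if `"ge"` to flag `values >= cutoff` (MI-style) or `"le"`
#'   to flag `values <= cutoff` (z-score-style).
#' @return List of class `cvf_classifier_eval`: `sensitivity` and
#'   `specificity` as integer percents, their unrounded counterparts
#'   (`sensitivity_raw`, `specificity_raw`), and the confusion counts.
#' @export
evaluate_classifier <- function(values, is_malingerer, cutoff,
                                flag_if = c("ge", "le")) {
  flag_if <- match.arg(flag_if)
  stopifnot(length(values) == length(is_malingerer))
  is_malingerer <- as.logical(is_malingerer)
  if (!any(is_malingerer) || all(is_malingerer))
    stop("both classes must be present to evaluate a classifier",
         call. = FALSE)
  flagged <- if (flag_if == "ge") values >= cutoff else values <= cutoff
  tp <- sum(flagged & is_malingerer)
  fn <- sum(!flagged & is_malingerer)
  tn <- sum(!flagged & !is_malingerer)
  fp <- sum(flagged & !is_malingerer)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(
    sensitivity = round(sens), specificity = round(spec),
    sensitivity_raw = sens, specificity_raw = spec,
    tp = tp, fn = fn, tn = tn, fp = fp
  ), class = "cvf_classifier_eval")
}

#' @export
print.cvf_classifier_eval <- function(x, ...) {
  cat(sprintf("<cvf_classifier_eval> sensitivity %d%% | specificity %d%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Published malingering sign panel
#'
#' The packaged reference panel of subjects with abnormal semantic-fluency
#' z-scores: 9 full-effort controls, 15 simulated malingerers, and 2 TBI
#' patients, each with the published z-score, the tail (0.05/0.10) at which
#' each of the five threshold signs fired, the normal-range-SOI flag, and
#' the published malingering-index total.
#'
#' @param include_tbi Keep the two TBI rows (excluded from classifier
#'   evaluation by default).
#' @return Data frame with columns `subject_id`, `group`, `z`, `syll`,
#'   `lwf`, `typ`, `tdp`, `pct_repeat` (tail levels, `NA` = not flagged),
#'   `n_soi` (0/1), `mi_printed`.
#' @export
malingering_signs_fixture <- function(include_tbi = FALSE) {
  df <- utils::read.delim(
    system.file("extdata", "malingering_signs.tsv", package = "cvfluency",
                mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("syll", "lwf", "typ", "tdp", "pct_repeat"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (!include_tbi) df <- df[df$group %in% c("control", "malingerer"), ]
  row.names(df) <- NULL
  df
}

#' Sign flags from a fixture row
#'
#' Converts one row of [malingering_signs_fixture()] into the logical flag
#' list consumed by [mi_total()].
#'
#' @param row One-row data frame (a fixture row).
#' @return Named list of six logical flags.
#' @export
fixture_row_flags <- function(row) {
  list(
    low_syllables = !is.na(row$syll),
    high_lwf = !is.na(row$lwf),
    high_typicality = !is.na(row$typ),
    high_repeats = !is.na(row$pct_repeat),
    tdp_abnormal = !is.na(row$tdp),
    soi_in_normal_range = row$n_soi == 1
  )
}
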