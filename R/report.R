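#' Assemble a full fluency report for one transcript
#'
#' Runs every configured analysis layer over the scoring window and returns
#' one panel: scoring, lexical, temporal, concept-vector semantics, Troyer
#' subcategory analysis (semantic "animals"-style conditions only),
#' demographic-adjusted z-score, and the malingering sign profile.  Layers
#' whose resources are absent are reported as `NULL` with an entry in
#' `$not_computed` rather than failing the whole report.
#'
#' @param t A [transcript()].
#' @param rule A [category_rule()] for correct-word scoring.
#' @param freq_table Optional [frequency_table()] (lexical layer).
#' @param typ_table Optional typicality table (cohort typicality).
#' @param store Optional [concept_store()] (semantic layer).
#' @param subcat_table Optional `cvf_subcategory_table` (Troyer layer).
#' @param norms Optional [norms_model()] (z-scores and sign profile).
#' @param window_s Scoring window in seconds (half-open).
#' @param threshold_fraction Switch threshold for [esa_summary()].
#' @param alpha One-tailed abnormality level for the z-score flag.
#' @param syllable_lexicon Passed to [lexical_summary()].
#' @return A list of class `cvf_fluency_report` with elements `subject_id`,
#'   `condition`, `score`, `lexical`, `temporal`, `esa`, `troyer`,
#'   `z`, `signs`, `not_computed`, and a `provenance` block recording the
#'   parameters.
#' @export
analyze <- function(t, rule, freq_table = NULL, typ_table = NULL,
                    store = NULL, subcat_table = NULL, norms = NULL,
                    window_s = t$duration_s, threshold_fraction = 0.75,
                    alpha = 0.05, syllable_lexicon = NULL) {
  stopifnot(inherits(t, "cvf_transcript"))
  score <- score_transcript(t, rule, window_s)
  tok <- t$events$token[t$events$onset_s < window_s]
  not_computed <- character(0)

  lexical <- NULL
  if (!is.null(freq_table) || !is.null(typ_table)) {
    lexical <- lexical_summary(t, freq_table, typ_table,
                               syllable_lexicon = syllable_lexicon,
                               window_s = window_s)
  } else not_computed <- c(not_computed, "lexical")

  temporal <- NULL
  if (score$total > 0L) {
    tw <- t
    tw$events <- tw$events[tw$events$onset_s < window_s, , drop = FALSE]
    tw$duration_s <- min(t$duration_s, window_s)
    temporal <- temporal_summary(tw, rule = rule)
  } else not_computed <- c(not_computed, "temporal")

  esa <- NULL
  if (!is.null(store)) {
    esa <- tryCatch(esa_summary(tok, store, threshold_fraction),
                    error = function(e) NULL)
    if (is.null(esa)) not_computed <- c(not_computed, "esa")
  } else not_computed <- c(not_computed, "esa")

  troyer <- NULL
  if (!is.null(subcat_table) && t$condition == "semantic") {
    troyer <- troyer_summary(tok, subcat_table, quiet = TRUE)
  } else not_computed <- c(not_computed, "troyer")

  z <- NULL
  if (!is.null(norms) && !is.null(norms[[t$condition]]) &&
      !is.na(t$demographics$education) &&
      !is.na(t$demographics$computer_use)) {
    pred <- predict_cw(t$demographics$education,
                       t$demographics$computer_use, t$condition, norms)
    zval <- z_score(score$correct, pred, norms[[t$condition]]$residual_sd)
    z <- list(z = zval, predicted_cw = pred,
              abnormal = flag_abnormal(zval, alpha), alpha = alpha)
  } else not_computed <- c(not_computed, "z")

  report <- structure(list(
    subject_id = t$subject_id, condition = t$condition,
    category_label = t$category_label,
    score = score, lexical = lexical, temporal = temporal,
    esa = esa, troyer = troyer, z = z, signs = NULL,
    not_computed = not_computed,
    provenance = list(
      window_s = window_s, threshold_fraction = threshold_fraction,
      alpha = alpha, duration_s = t$duration_s,
      tool = "cvfluency",
      version = as.character(utils::packageVersion("cvfluency")))
  ), class = "cvf_fluency_report")

  if (!is.null(norms) && t$condition == "semantic" &&
      !is.null(lexical) && !is.null(temporal) && !is.null(esa) &&
      !is.null(norms$thresholds)) {
    report$signs <- sign_profile(report, norms)
  } else report$not_computed <- c(report$not_computed, "signs")
  report
}

#' @export
print.cvf_fluency_report <- function(x, ...) {
  cat(sprintf("<cvf_fluency_report> %s | %s (%s)\n", x$subject_id,
              x$condition, x$category_label))
  s <- x$score
  cat(sprintf("  correct %d / total %d | repeats %.1f%% | out %d\n",
              s$correct, s$total, s$pct_repeats, s$out_of_category))
  if (!is.null(x$lexical))
    cat(sprintf("  LWF %.2f | Syll %.2f | Typ %s\n", x$lexical$mean_lwf,
                x$lexical$mean_syllables,
                if (is.na(x$lexical$typicality_pct)) "NA"
                else sprintf("%.1f%%", x$lexical$typicality_pct)))
  if (!is.null(x$temporal)) cat(sprintf("  TDP %.1f%%\n", x$temporal$tdp))
  if (!is.null(x$esa))
    cat(sprintf("  PW-ESA %.3f | A-ESA %.3f | SOI %.2f | switches %d\n",
                x$esa$pw_esa, x$esa$a_esa, x$esa$soi, x$esa$n_switches))
  if (!is.null(x$troyer))
    cat(sprintf("  Troyer switches %d | multi-word clusters %d (mean %.1f)\n",
                x$troyer$n_switches, x$troyer$n_multiword_clusters,
                x$troyer$mean_multiword_cluster_size))
  if (!is.null(x$z))
    cat(sprintf("  z %.2f (%s)\n", x$z$z,
                if (x$z$abnormal) "abnormal" else "normal"))
  if (!is.null(x$signs))
    cat(sprintf("  malingering index %d\n", x$signs$mi_total))
  if (length(x$not_computed))
    cat("  not computed:", paste(x$not_computed, collapse = ", "), "\n")
  invisible(x)
}

#' Analyze a cohort of transcripts
#'
#' Builds the within-cohort typicality table first, then produces one
#' report per subject.  When `norms = "fit"` the normative model is fitted
#' to the cohort itself before z-scoring; when malingering labels are given
#' the malingering-index classifier is evaluated against them.
#'
#' @param transcripts List of [transcript()] objects (one category).
#' @param rule,freq_table,store,subcat_table,window_s,threshold_fraction,alpha
#'   Passed to [analyze()].
#' @param norms A [norms_model()], `"fit"` to fit on this cohort, or `NULL`.
#' @param labels Optional logical vector (or named by subject id):
#'   `TRUE` = malingerer; triggers classifier evaluation at `mi_cutoff`.
#' @param mi_cutoff Malingering-index cutoff for the classifier.
#' @return A list of class `cvf_cohort_analysis`: `reports` (named by
#'   subject id), `typicality_table`, `norms` (input or fitted),
#'   `summary` (one data-frame row of panel metrics per subject), and
#'   `classifier` (a [evaluate_classifier()] result or `NULL`).
#' @export
cohort_analyze <- function(transcripts, rule, freq_table = NULL,
                           store = NULL, subcat_table = NULL,
                           norms = NULL, labels = NULL,
                           window_s = NULL, threshold_fraction = 0.75,
                           alpha = 0.05, mi_cutoff = 3L) {
  stopifnot(length(transcripts) >= 1L,
            all(vapply(transcripts, inherits, logical(1),
                       "cvf_transcript")))
  typ <- build_typicality_table(transcripts)

  fit_requested <- identical(norms, "fit")
  run <- function(nrm) lapply(transcripts, function(t)
    analyze(t, rule, freq_table = freq_table, typ_table = typ,
            store = store, subcat_table = subcat_table, norms = nrm,
            window_s = if (is.null(window_s)) t$duration_s else window_s,
            threshold_fraction = threshold_fraction, alpha = alpha))

  if (fit_requested) {
    pre <- run(NULL)
    df <- cohort_summary_frame(pre, transcripts)
    norms <- fit_norms(df, condition = transcripts[[1]]$condition)
  }
  reports <- run(norms)
  names(reports) <- vapply(transcripts, `[[`, character(1), "subject_id")
  summary <- cohort_summary_frame(reports, transcripts)

  classifier <- NULL
  if (!is.null(labels)) {
    if (!is.null(names(labels)))
      labels <- labels[names(reports)]
    mi <- vapply(reports, function(r)
      if (is.null(r$signs)) NA_integer_ else r$signs$mi_total, integer(1))
    keep <- !is.na(mi)
    classifier <- evaluate_classifier(mi[keep], labels[keep], mi_cutoff,
                                      flag_if = "ge")
  }
  structure(list(reports = reports, typicality_table = typ, norms = norms,
                 summary = summary, classifier = classifier),
            class = "cvf_cohort_analysis")
}

cohort_summary_frame <- function(reports, transcripts) {
  grab <- function(f) vapply(seq_along(reports), function(i)
    f(reports[[i]], transcripts[[i]]), numeric(1))
  data.frame(
    subject_id = vapply(transcripts, `[[`, character(1), "subject_id"),
    age = grab(function(r, t) as.numeric(t$demographics$age)),
    education = grab(function(r, t) as.numeric(t$demographics$education)),
    computer_use = grab(function(r, t)
      as.numeric(t$demographics$computer_use)),
    cw = grab(function(r, t) as.numeric(r$score$correct)),
    pct_repeats = grab(function(r, t) r$score$pct_repeats),
    mean_lwf = grab(function(r, t)
      if (is.null(r$lexical)) NA_real_ else r$lexical$mean_lwf),
    mean_syllables = grab(function(r, t)
      if (is.null(r$lexical)) NA_real_ else r$lexical$mean_syllables),
    typicality_pct = grab(function(r, t)
      if (is.null(r$lexical)) NA_real_ else r$lexical$typicality_pct),
    tdp = grab(function(r, t)
      if (is.null(r$temporal)) NA_real_ else r$temporal$tdp),
    soi = grab(function(r, t)
      if (is.null(r$esa)) NA_real_ else r$esa$soi),
    n_switches = grab(function(r, t)
      if (is.null(r$esa)) NA_real_ else as.numeric(r$esa$n_switches)),
    z = grab(function(r, t) if (is.null(r$z)) NA_real_ else r$z$z),
    mi_total = grab(function(r, t)
      if (is.null(r$signs)) NA_real_ else as.numeric(r$signs$mi_total)),
    stringsAsFactors = FALSE)
}

#' Write / read a fluency report as JSON
#'
#' Reports round-trip: a serialized report re-parsed with
#' [read_report_json()] compares equal to the in-memory panel values.
#'
#' @param report A `cvf_fluency_report`.
#' @param path Output path.
#' @return `write_report_json()` returns `path` invisibly;
#'   `read_report_json()` returns the report list.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cvf_fluency_report"))
  x <- unclass(report)
  x$score <- unclass(x$score)
  for (f in c("lexical", "temporal", "esa", "troyer", "signs"))
    if (!is.null(x[[f]])) x[[f]] <- unclass(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("score", "lexical", "temporal", "esa", "troyer", "signs"))
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  structure(x, class = "cvf_fluency_report")
}

#' Flat one-row summary of a report (for TSV export)
#'
#' @param report A `cvf_fluency_report`.
#' @return One-row data frame of the headline metrics.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "cvf_fluency_report"))
  g <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  data.frame(
    subject_id = report$subject_id, condition = report$condition,
    total = report$score$total, correct = report$score$correct,
    repeats = report$score$repeats,
    pct_repeats = report$score$pct_repeats,
    out_of_category = report$score$out_of_category,
    mean_lwf = g(report$lexical$mean_lwf),
    mean_syllables = g(report$lexical$mean_syllables),
    typicality_pct = g(report$lexical$typicality_pct),
    tdp = g(report$temporal$tdp),
    pw_esa = g(report$esa$pw_esa), a_esa = g(report$esa$a_esa),
    soi = g(report$esa$soi), esa_switches = g(report$esa$n_switches),
    esa_multiword_clusters = g(report$esa$n_multiword_clusters),
    esa_mean_cluster_size = g(report$esa$mean_multiword_cluster_size),
    troyer_switches = g(report$troyer$n_switches),
    troyer_multiword_clusters = g(report$troyer$n_multiword_clusters),
    troyer_mean_cluster_size = g(report$troyer$mean_multiword_cluster_size),
    z = g(report$z$z), mi_total = g(report$signs$mi_total),
    stringsAsFactors = FALSE)
}
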