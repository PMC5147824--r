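#' Construct a normative model
#'
#' Holds everything needed to convert raw fluency measures into
#' demographic-adjusted z-scores and control-distribution sign flags: per
#' condition a linear regression of correct words on education and daily
#' computer use plus the residual standard deviation; tail thresholds of
#' the control distribution at p = 0.05 and p = 0.10 for the five ancillary
#' measures; and the normative mean/SD of the semantic organization index.
#'
#' @param semantic,phonemic Lists with `intercept`, `coef_education`,
#'   `coef_computer_use`, `residual_sd` (> 0).  Either may be `NULL`.
#' @param thresholds Named list (per measure: `mean_syllables`, `mean_lwf`,
#'   `typicality_pct`, `pct_repeats`, `tdp`) of lists with `tail`
#'   (`"lower"` or `"upper"`), `p05`, `p10`; the p05 threshold must be at
#'   least as extreme as the p10 threshold in the stated tail direction.
#' @param soi_mean,soi_sd Normative SOI mean and standard deviation.
#' @return An object of class `cvf_norms_model`.
#' @seealso [default_norms()], [fit_norms()], [read_norms()]
#' @export
norms_model <- function(semantic = NULL, phonemic = NULL,
                        thresholds = NULL, soi_mean = NA_real_,
                        soi_sd = NA_real_) {
  chk_cond <- function(x, label) {
    if (is.null(x)) return(NULL)
    need <- c("intercept", "coef_education", "coef_computer_use",
              "residual_sd")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop(sprintf("%s condition: missing field(s) %s", label,
                   paste(miss, collapse = ", ")), call. = FALSE)
    if (!is.numeric(x$residual_sd) || x$residual_sd <= 0)
      stop(sprintf("%s condition: residual_sd must be > 0", label),
           call. = FALSE)
    x[need]
  }
  if (!is.null(thresholds)) {
    for (m in names(thresholds)) {
      th <- thresholds[[m]]
      if (!th$tail %in% c("lower", "upper"))
        stop(sprintf("threshold '%s': tail must be lower/upper", m),
             call. = FALSE)
      extreme_ok <- if (th$tail == "lower") th$p05 <= th$p10
                    else th$p05 >= th$p10
      if (!extreme_ok)
        stop(sprintf("threshold '%s': p05 must be more extreme than p10", m),
             call. = FALSE)
    }
  }
  structure(list(
    semantic = chk_cond(semantic, "semantic"),
    phonemic = chk_cond(phonemic, "phonemic"),
    thresholds = thresholds,
    soi_mean = soi_mean, soi_sd = soi_sd
  ), class = "cvf_norms_model")
}

#' Bundled default normative model
#'
#' Loads the normative configuration shipped with the package: the
#' published 90-s regression equations for the "animals" and letter-"F"
#' conditions, residual SDs derived from the cohort summary statistics, and
#' normal-approximation control-tail thresholds (see the file's comments
#' for provenance).
#'
#' @return A [norms_model()].
#' @export
default_norms <- function() {
  read_norms(system.file("extdata", "default_norms.yaml",
                         package = "cvfluency", mustWork = TRUE))
}

#' Read / write a normative model (YAML or JSON)
#'
#' The on-disk layout mirrors the [norms_model()] fields.  Format is picked
#' by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File path.
#' @return [read_norms()] returns a `cvf_norms_model`; `write_norms()`
#'   returns `path` invisibly.
#' @export
read_norms <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  norms_model(semantic = x$semantic, phonemic = x$phonemic,
              thresholds = x$thresholds,
              soi_mean = x$soi_mean %||% NA_real_,
              soi_sd = x$soi_sd %||% NA_real_)
}

#' @rdname read_norms
#' @param norms A `cvf_norms_model`.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "cvf_norms_model"))
  x <- unclass(norms)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            na = "null")
  invisible(path)
}

#' Predicted correct-word score from demographics
#'
#' Evaluates the normative regression `CW = intercept +
#' coef_education * education + coef_computer_use * computer_use` for the
#' requested condition.
#'
#' @param education Years of education.
#' @param computer_use Daily computer use (Likert 1--8).
#' @param condition `"semantic"` or `"phonemic"`.
#' @param norms A [norms_model()] (default: [default_norms()]).
#' @return Expected correct-word count (vectorized over inputs).
#' @examples
#' predict_cw(14.5, 5.1, "semantic")
#' @export
predict_cw <- function(education, computer_use,
                       condition = c("semantic", "phonemic"),
                       norms = default_norms()) {
  condition <- match.arg(condition)
  cf <- norms[[condition]]
  if (is.null(cf))
    stop(sprintf("norms model lacks the %s condition", condition),
         call. = FALSE)
  cf$intercept + cf$coef_education * education +
    cf$coef_computer_use * computer_use
}

#' Demographic-adjusted z-score
#'
#' @param observed_cw Observed correct-word count.
#' @param predicted_cw Expected count from [predict_cw()].
#' @param residual_sd Residual standard deviation of the normative
#'   regression (> 0).
#' @return `(observed - predicted) / residual_sd`.
#' @export
z_score <- function(observed_cw, predicted_cw, residual_sd) {
  if (!is.numeric(residual_sd) || any(residual_sd <= 0))
    stop("`residual_sd` must be > 0", call. = FALSE)
  (observed_cw - predicted_cw) / residual_sd
}

#' One-tailed abnormality flag
#'
#' A z-score is abnormal when it falls below the one-tailed standard-normal
#' quantile of `alpha` (deficit direction only): -1.645 at alpha = 0.05.
#'
#' @param z Numeric vector of z-scores.
#' @param alpha One-tailed significance level in (0, 0.5).
#' @return Logical vector.
#' @export
flag_abnormal <- function(z, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  z < stats::qnorm(alpha)
}

#' Fit a normative model to a control cohort
#'
#' Ordinary least squares of correct words on education and computer use;
#' the residual SD comes from the fit residuals.  Tail thresholds for the
#' ancillary measures are empirical nearest-rank percentiles of the control
#' distribution, and the SOI mean/SD are cohort moments.
#'
#' @param data Data frame with one row per control subject: `cw`,
#'   `education`, `computer_use`, and optionally `mean_syllables`,
#'   `mean_lwf`, `typicality_pct`, `pct_repeats`, `tdp`, `soi`.
#' @param condition Which condition slot of the model to fill.
#' @return A [norms_model()] with the fitted condition, thresholds for
#'   whichever measure columns are present, and (given `soi`) SOI moments.
#'   The fitted `lm` object is attached as attribute `"fit"`.
#' @export
fit_norms <- function(data, condition = c("semantic", "phonemic")) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(data))
  need <- c("cw", "education", "computer_use")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) < 3L)
    stop("need at least 3 subjects to fit norms", call. = FALSE)
  if (stats::sd(data$education) == 0 || stats::sd(data$computer_use) == 0 ||
      abs(stats::cor(data$education, data$computer_use)) > 0.999)
    stop("degenerate or collinear predictors", call. = FALSE)
  fit <- stats::lm(cw ~ education + computer_use, data = data)
  cf <- stats::coef(fit)
  cond <- list(intercept = unname(cf[1]),
               coef_education = unname(cf["education"]),
               coef_computer_use = unname(cf["computer_use"]),
               residual_sd = stats::sd(stats::residuals(fit)))
  # nearest-rank (inverse ECDF) percentiles of the control distribution
  tails <- list(mean_syllables = "lower", mean_lwf = "upper",
                typicality_pct = "upper", pct_repeats = "upper",
                tdp = "upper")
  thresholds <- NULL
  for (m in names(tails)) {
    if (!m %in% names(data)) next
    x <- data[[m]][!is.na(data[[m]])]
    if (!length(x)) next
    q <- function(p) {
      pp <- if (tails[[m]] == "lower") p else 1 - p
      unname(stats::quantile(x, pp, type = 1))
    }
    thresholds[[m]] <- list(tail = tails[[m]], p05 = q(0.05), p10 = q(0.10))
  }
  nm <- norms_model(
    semantic = if (condition == "semantic") cond else NULL,
    phonemic = if (condition == "phonemic") cond else NULL,
    thresholds = thresholds,
    soi_mean = if ("soi" %in% names(data)) mean(data$soi, na.rm = TRUE)
               else NA_real_,
    soi_sd = if ("soi" %in% names(data)) stats::sd(data$soi, na.rm = TRUE)
             else NA_real_)
  attr(nm, "fit") <- fit
  nm
}
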