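#' Longitudinal covariate-adjusted association
#'
#' Regresses a follow-up cognitive score on a baseline predictor with the
#' longitudinal covariate set: age, sex, education, baseline WMH volume,
#' follow-up duration, and the baseline score of the same test (the
#' column named like the outcome without its `_fu` suffix, unless given).
#'
#' @param tab cohort data.frame subset to the stratum of interest.
#' @param outcome_followup follow-up score column (conventionally
#'   `<test>_fu`).
#' @param predictor baseline predictor column (e.g. a network coupling).
#' @param baseline explicit baseline-score column; default strips `_fu`.
#' @param stratum label recorded in the result.
#' @return one-row association data.frame, see [linear_assoc()].
#' @export
longitudinal_assoc <- function(tab, outcome_followup, predictor,
                               baseline = sub("_fu$", "", outcome_followup),
                               stratum = "all") {
  if (!"follow_up_duration" %in% names(tab))
    stop("missing follow_up_duration column")
  if (!outcome_followup %in% names(tab))
    stop("missing follow-up column '", outcome_followup, "'")
  if (baseline == outcome_followup || !baseline %in% names(tab))
    stop("cannot resolve baseline score column for '", outcome_followup, "'")
  fu <- tab[!is.na(tab[[outcome_followup]]), , drop = FALSE]
  if (nrow(fu) == 0L) stop("no subjects with follow-up data")
  covs <- covariate_sets("longitudinal")
  covs[covs == "baseline_score"] <- baseline
  linear_assoc(fu, outcome_followup, predictor, covariates = covs,
               stratum = stratum)
}

#' Quartile outcome labels
#'
#' Splits follow-up scores into the upper quartile (`>= Q3`), the lower
#' quartile (`<= Q1`) and the excluded middle. Quartiles use the
#' inclusive linear-interpolation definition (R quantile type 7); ties at
#' a boundary all fall on the extreme side.
#'
#' @param scores numeric vector, n >= 8 observed values, nonconstant.
#' @return character vector aligned with `scores`: `"upper"`, `"lower"`,
#'   `"excluded"` (`NA` preserved).
#' @examples
#' quartile_labels(1:8)  # lower, lower, excluded x4, upper, upper
#' @export
quartile_labels <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 8L) stop("need at least 8 observed scores")
  if (length(unique(obs)) < 2L)
    stop("scores are constant; quartiles degenerate")
  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE, type = 7)
  out <- rep(NA_character_, length(scores))
  out[!is.na(scores) & scores <= q[1]] <- "lower"
  out[!is.na(scores) & scores >= q[2]] <- "upper"
  out[!is.na(scores) & scores > q[1] & scores < q[2]] <- "excluded"
  out
}

#' ROC analysis with a sensitivity-targeted cutoff
#'
#' Discriminates the upper from the lower quartile class using a
#' continuous predictor. AUC is the rank (Mann-Whitney) area with tie
#' correction; the orientation follows the hypothesis that a higher
#' predictor marks the positive class, so AUC < 0.5 is reported as is,
#' never flipped. The 95% CI uses the DeLong asymptotic method by default
#' (seeded bootstrap available). The operating cutoff is the point with
#' the highest Youden index among points whose sensitivity is at least
#' `sens_floor` (a sensitivity-prioritized rule; plain Youden if no point
#' reaches the floor). `predictor >= cutoff` predicts the positive class.
#'
#' @param predictor numeric vector.
#' @param labels class labels aligned with `predictor`; rows not equal to
#'   `positive`/`negative` (e.g. `"excluded"`, `NA`) are dropped.
#' @param positive,negative class labels (defaults `"upper"`/`"lower"`).
#' @param sens_floor minimum sensitivity for the cutoff search (default
#'   0.90).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap resamples (when `ci_method = "bootstrap"`).
#' @param seed seed for the bootstrap.
#' @return object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`,
#'   and `coords` (data.frame of the full empirical ROC: `threshold`,
#'   `sensitivity`, `specificity`).
#' @export
roc_analysis <- function(predictor, labels, positive = "upper",
                         negative = "lower", sens_floor = 0.90,
                         ci_method = c("delong", "bootstrap"),
                         boot_n = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(predictor) & !is.na(labels) & labels %in% c(positive, negative)
  x <- predictor[keep]
  y <- as.character(labels[keep])
  n_pos <- sum(y == positive); n_neg <- sum(y == negative)
  if (n_pos < 2L || n_neg < 2L)
    stop("need at least 2 subjects in each class (got ",
         n_pos, " positive, ", n_neg, " negative)")
  r <- pROC::roc(response = y, predictor = x,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(r, method = "delong"))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n, progress = "none")
  }
  co <- pROC::coords(r, x = "all",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  finite <- is.finite(co$threshold)
  cand <- co[finite & co$sensitivity >= sens_floor, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- co[finite, , drop = FALSE]
  youden <- cand$sensitivity + cand$specificity - 1
  best <- cand[which.max(youden), ]
  structure(list(auc = auc, ci_low = as.numeric(ci[1]),
                 ci_high = as.numeric(ci[3]),
                 cutoff = best$threshold, sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 n_pos = n_pos, n_neg = n_neg, coords = co),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), n = %d vs %d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("cutoff = %.3f: sensitivity %.3f, specificity %.3f\n",
              x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
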