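#' Classify WMH severity from Fazekas scores
#'
#' Severe WMH is a periventricular (PWMH) Fazekas score of 3 or a deep
#' (DWMH) score >= 2; otherwise mild. Subjects with both scores zero have
#' no WMH and are not includable.
#'
#' @param pwmh,dwmh integer Fazekas scores in 0..3 (vectorized).
#' @return character vector, `"mild"` or `"severe"`.
#' @examples
#' classify_severity(c(3, 2, 0), c(0, 1, 2))  # severe, mild, severe
#' @export
classify_severity <- function(pwmh, dwmh) {
  if (length(pwmh) != length(dwmh)) stop("pwmh and dwmh lengths differ")
  if (!all(pwmh %in% 0:3) || !all(dwmh %in% 0:3))
    stop("Fazekas scores must be integers in 0..3")
  both0 <- pwmh == 0 & dwmh == 0
  if (any(both0))
    stop("subject(s) with PWMH = DWMH = 0 do not meet inclusion ",
         "(WMH Fazekas scores > 0): index ",
         paste(which(both0), collapse = ", "))
  ifelse(pwmh == 3 | dwmh >= 2, "severe", "mild")
}

#' Standardize cognitive test scores
#'
#' Transforms each named column to a z-score (mean 0, SD 1 with the n-1
#' denominator) over its observed values; missing values are ignored in
#' the moments and preserved in place.
#'
#' @param tab data.frame.
#' @param cols character vector of columns to standardize.
#' @return `tab` with the named columns standardized.
#' @export
zscore_battery <- function(tab, cols) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cl in cols) {
    x <- tab[[cl]]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2L)
      stop("test '", cl, "' is constant; cannot standardize")
    tab[[cl]] <- (x - mean(obs)) / stats::sd(obs)
  }
  tab
}

# coerce a cohort column to numeric for modeling: sex -> 0/1 (male = 1),
# logicals -> 0/1, otherwise must already be numeric
model_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    u <- sort(unique(x[!is.na(x)]))
    if (identical(u, c("female", "male")))
      return(as.numeric(x == "male"))
    if (length(u) == 2L) return(as.numeric(x == u[2L]))
  }
  stop("cannot use column '", name, "' as a numeric model term")
}

#' Between-group comparison battery
#'
#' Compares each variable between two strata: pooled-variance two-sample
#' t-tests for continuous variables, chi-square tests (with Yates
#' continuity correction for the 2x2 table, switchable) for binary
#' variables.
#'
#' @param tab cohort data.frame.
#' @param variables columns to compare.
#' @param group grouping column (default `"severity"`), must have exactly
#'   two levels with n >= 2 each.
#' @param correct use the continuity correction in 2x2 chi-square tests.
#' @return data.frame: `variable`, `type` (`t`/`chisq`), `statistic`, `p`,
#'   `n`.
#' @export
compare_groups <- function(tab, variables, group = "severity",
                           correct = TRUE) {
  g <- tab[[group]]
  if (is.null(g)) stop("no grouping column '", group, "'")
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2L) stop("grouping must have exactly two levels")
  if (any(table(g) < 2L)) stop("each stratum needs n >= 2")
  rows <- lapply(variables, function(v) {
    x <- tab[[v]]
    if (is.null(x)) stop("no column '", v, "'")
    ok <- !is.na(x) & !is.na(g)
    binary <- is.logical(x) ||
      (length(unique(x[ok])) == 2L && (is.character(x) || is.factor(x))) ||
      (is.numeric(x) && all(x[ok] %in% c(0, 1)))
    if (binary) {
      xt <- table(factor(g[ok], levels = lev), x[ok])
      ts <- suppressWarnings(stats::chisq.test(xt, correct = correct))
      data.frame(variable = v, type = "chisq",
                 statistic = unname(ts$statistic), p = ts$p.value,
                 n = sum(ok), stringsAsFactors = FALSE)
    } else {
      ts <- stats::t.test(x[ok][g[ok] == lev[1]], x[ok][g[ok] == lev[2]],
                          var.equal = TRUE)
      data.frame(variable = v, type = "t",
                 statistic = unname(ts$statistic), p = ts$p.value,
                 n = sum(ok), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Named covariate sets of the analysis battery
#'
#' Each analysis stage adjusts for a fixed, ordered covariate list:
#' group comparisons of coupling and the WMH-volume models use age and
#' sex; the fully adjusted WMH-volume model adds education and the five
#' vascular risk factors; coupling-cognition models use age, sex,
#' education and WMH volume; longitudinal models add follow-up duration
#' and the baseline score of the outcome.
#'
#' @param analysis one of `"group_compare"`, `"wmh_coupling"`,
#'   `"wmh_coupling_full"`, `"coupling_cognition"`, `"longitudinal"`.
#' @return ordered character vector of covariate column names (the
#'   longitudinal set contains the placeholder `"baseline_score"`, to be
#'   substituted with the outcome's baseline column).
#' @export
covariate_sets <- function(analysis) {
  sets <- list(
    group_compare      = c("age", "sex"),
    wmh_coupling       = c("age", "sex"),
    wmh_coupling_full  = c("age", "sex", "education", "hypertension",
                           "diabetes", "hypercholesterolemia", "smoking",
                           "drinking"),
    coupling_cognition = c("age", "sex", "education", "wmh_volume"),
    longitudinal       = c("age", "sex", "education", "wmh_volume",
                           "follow_up_duration", "baseline_score"))
  if (!analysis %in% names(sets))
    stop("unknown analysis '", analysis, "'; one of: ",
         paste(names(sets), collapse = ", "))
  sets[[analysis]]
}

#' Covariate-adjusted linear association with standardized beta
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates over
#' complete cases. The reported coefficient is the standardized beta,
#' `b * sd(predictor) / sd(outcome)`, applied uniformly to every predictor
#' including binary ones (the convention under which standard statistical
#' packages print "Beta"). The two-sided p-value is for the predictor of
#' interest.
#'
#' @param tab cohort data.frame (already joined with coupling values if
#'   needed).
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names.
#' @param stratum label recorded in the result (default `"all"`); the
#'   table is assumed already subset.
#' @return one-row data.frame (an association result): `stratum`,
#'   `outcome`, `predictor`, `covariates`, `beta_std`, `se_std`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_fdr` (`NA` until a family adjustment), `n`.
#' @export
linear_assoc <- function(tab, outcome, predictor, covariates = character(),
                         stratum = "all") {
  vars <- c(outcome, predictor, covariates)
  miss <- setdiff(vars, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  mm <- lapply(vars, function(v) model_numeric(tab[[v]], v))
  names(mm) <- paste0("v", seq_along(vars))  # syntactic-safe names
  d <- as.data.frame(mm)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(covariates) + 3L)
    stop("too few complete cases (", nrow(d), ") for ",
         length(covariates), " covariates")
  fit <- stats::lm(stats::reformulate(names(d)[-1L], response = "v1"),
                   data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    aliased <- vars[-1L][is.na(cf[-1L])]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  sdx <- stats::sd(d$v2)
  sdy <- stats::sd(d$v1)
  if (sdx == 0 || sdy == 0) stop("constant outcome or predictor")
  scale <- sdx / sdy
  b <- sm["v2", "Estimate"] * scale
  se <- sm["v2", "Std. Error"] * scale
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  data.frame(stratum = stratum, outcome = outcome, predictor = predictor,
             covariates = paste(covariates, collapse = "+"),
             beta_std = b, se_std = se,
             ci_low = b - tcrit * se, ci_high = b + tcrit * se,
             p_raw = sm["v2", "Pr(>|t|)"], p_fdr = NA_real_,
             n = nrow(d), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1. One
#' family is one stratum's test table (e.g. the seven network models of
#' one subgroup).
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @return adjusted p-values, same length and order.
#' @examples
#' fdr_bh(c(0.006, 0.050))  # 0.012, 0.050
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors; complete pairs used, n >= 3 required.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Repeated-measures ANOVA across networks
#'
#' One-way within-subject ANOVA on the subjects x networks coupling
#' matrix, with the Greenhouse-Geisser sphericity correction applied to
#' both degrees of freedom (so df1 = epsilon * (k - 1)). Post hoc,
#' all-pairs paired comparisons are reported as t-values with Tukey-HSD
#' family adjustment on the pooled within-subject error.
#'
#' @param mat N x k numeric matrix, one complete row per subject (columns
#'   should be named by network). Missing cells are an error; no
#'   imputation.
#' @return object of class `rm_anova`: list with `F`, `df1`, `df2`
#'   (corrected), `epsilon`, `p`, `grand_mean`, `means`, `n`, `k`, and
#'   `posthoc` (data.frame: `a`, `b`, `t`, `p_adj`).
#' @export
rm_anova_networks <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells; repeated-measures ANOVA needs ",
                       "complete network vectors per subject")
  N <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need at least 2 networks")
  if (N < 3L) stop("need at least 3 subjects")
  grand <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_net <- N * sum((col_m - grand)^2)
  resid <- mat - outer(row_m, rep(1, k)) -
    outer(rep(1, N), col_m) + grand
  ss_err <- sum(resid^2)
  df_net <- k - 1
  df_err <- (N - 1) * (k - 1)
  ms_net <- ss_net / df_net
  ms_err <- ss_err / df_err
  f_stat <- if (ms_err == 0) {
    if (ms_net == 0) 0 else Inf
  } else ms_net / ms_err
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(mat)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  tr <- sum(diag(Sdc))
  eps <- if (sum(Sdc^2) == 0) 1 else tr^2 / ((k - 1) * sum(Sdc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  df1 <- eps * df_net
  df2 <- eps * df_err
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  # Tukey-adjusted all-pairs paired comparisons on the pooled error
  pairs <- utils::combn(k, 2)
  nm <- colnames(mat)
  if (is.null(nm)) nm <- paste0("net", seq_len(k))
  tval <- (col_m[pairs[1, ]] - col_m[pairs[2, ]]) / sqrt(2 * ms_err / N)
  p_adj <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k, df = df_err,
                         lower.tail = FALSE)
  posthoc <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]],
                        t = unname(tval), p_adj = unname(p_adj),
                        stringsAsFactors = FALSE)
  structure(list(F = f_stat, df1 = df1, df2 = df2, epsilon = eps, p = p,
                 grand_mean = grand, means = col_m, n = N, k = k,
                 posthoc = posthoc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%.2f, %.0f) = %.1f, p %s (GG eps = %.3f)\n",
              x$df1, x$df2, x$F,
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p),
              x$epsilon))
  invisible(x)
}
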