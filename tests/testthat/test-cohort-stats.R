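test_that("severity rule: PWMH 3 or DWMH >= 2 is severe", {
  expect_equal(classify_severity(3, 0), "severe")
  expect_equal(classify_severity(2, 1), "mild")
  expect_equal(classify_severity(0, 2), "severe")
  expect_equal(classify_severity(c(1, 3, 2), c(1, 3, 2)),
               c("mild", "severe", "severe"))
  expect_error(classify_severity(0, 0), "inclusion")
  expect_error(classify_severity(4, 1), "0..3")
})

test_that("z-scoring is exact, idempotent and preserves missing values", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, NA, 7), cst = c(2, 2, 2))
  out <- zscore_battery(tab, c("a", "b"))
  expect_equal(out$a, c(-1, 0, 1))
  expect_true(is.na(out$b[2]))
  expect_equal(mean(out$b, na.rm = TRUE), 0)
  expect_equal(sd(out$b, na.rm = TRUE), 1)
  again <- zscore_battery(out, "a")
  expect_equal(again$a, out$a, tolerance = 1e-12)
  expect_error(zscore_battery(tab, "cst"), "cst")
})

test_that("group comparisons: pooled t for continuous, Yates chi-square for binary", {
  set.seed(2)
  n1 <- 15; n2 <- 12
  tab <- data.frame(severity = rep(c("mild", "severe"), c(n1, n2)),
                    x = c(rnorm(n1, 0), rnorm(n2, 1)),
                    flag = rbinom(n1 + n2, 1, 0.5))
  res <- compare_groups(tab, c("x", "flag"))
  # pooled-t closed form from summary statistics
  x1 <- tab$x[1:n1]; x2 <- tab$x[-(1:n1)]
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t_oracle <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$statistic[res$variable == "x"], t_oracle,
               tolerance = 1e-12)
  expect_equal(res$p[res$variable == "x"],
               2 * pt(-abs(t_oracle), n1 + n2 - 2), tolerance = 1e-12)
  expect_equal(res$type, c("t", "chisq"))
  # identical groups: t = 0, p = 1
  tab2 <- data.frame(severity = rep(c("mild", "severe"), each = 5),
                     x = rep(1:5, 2))
  r2 <- compare_groups(tab2, "x")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
})

test_that("standardized beta identities hold", {
  set.seed(6)
  tab <- data.frame(y = rnorm(50))
  tab$x <- tab$y
  r <- suppressWarnings(linear_assoc(tab, "y", "x"))  # exact fit
  expect_equal(r$beta_std, 1, tolerance = 1e-12)
  expect_lt(r$p_raw, 1e-12)
  # single predictor: beta_std equals Pearson r
  tab2 <- data.frame(y = rnorm(40), x = rnorm(40))
  r2 <- linear_assoc(tab2, "y", "x")
  pa <- pearson_assoc(tab2$x, tab2$y)
  expect_equal(r2$beta_std, pa$r, tolerance = 1e-12)
  expect_equal(r2$p_raw, pa$p, tolerance = 1e-12)
  expect_equal(r2$n, 40L)
})

test_that("rank-deficient designs are reported with the aliased column", {
  set.seed(7)
  tab <- data.frame(y = rnorm(30), x = rnorm(30))
  tab$z <- 2 * tab$x
  expect_error(linear_assoc(tab, "y", "x", covariates = "z"), "aliased: z")
})

test_that("binary predictors get the same sd-ratio standardization", {
  set.seed(8)
  tab <- data.frame(y = rnorm(60),
                    sex = sample(c("female", "male"), 60, replace = TRUE))
  r <- linear_assoc(tab, "y", "sex")
  xn <- as.numeric(tab$sex == "male")
  b <- coef(lm(tab$y ~ xn))[2]
  expect_equal(r$beta_std, unname(b) * sd(xn) / sd(tab$y),
               tolerance = 1e-12)
})

test_that("covariate sets match the analysis battery definitions", {
  expect_equal(covariate_sets("coupling_cognition"),
               c("age", "sex", "education", "wmh_volume"))
  expect_equal(covariate_sets("longitudinal"),
               c("age", "sex", "education", "wmh_volume",
                 "follow_up_duration", "baseline_score"))
  expect_equal(covariate_sets("wmh_coupling"), c("age", "sex"))
  expect_length(covariate_sets("wmh_coupling_full"), 8L)
  expect_error(covariate_sets("nope"), "unknown analysis")
})

test_that("BH adjustment matches the step-up definition and its properties", {
  # direct-definition oracle: sort, p * m / rank, cumulative min from top
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(10)
  for (i in 1:20) {
    p <- runif(10)
    expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(fdr_bh(0.3), 0.3)
  p <- runif(8)
  expect_true(all(fdr_bh(p) >= p))                      # adjusted >= raw
  # order-preserving: adjusted values are nondecreasing along sorted raw p
  expect_true(all(diff(fdr_bh(p)[order(p)]) >= -1e-15))
  expect_true(all(fdr_bh(p) <= 1))
  # smallest p scales by m when it stays the minimum after adjustment
  expect_equal(fdr_bh(c(0.001, 0.5, 0.6, 0.7))[1], 0.004)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pearson_assoc hits the closed-form t transform", {
  expect_equal(pearson_assoc(1:10, 1:10)$r, 1)
  expect_equal(pearson_assoc(1:10, -(1:10))$r, -1)
  set.seed(12)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50)
  pa <- pearson_assoc(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(48 / (1 - r^2))
  expect_equal(pa$r, r, tolerance = 1e-12)
  expect_equal(pa$p, 2 * pt(-abs(tt), 48), tolerance = 1e-12)
  expect_error(pearson_assoc(rep(1, 5), rnorm(5)), "constant")
})

test_that("repeated-measures ANOVA matches the decomposition oracle", {
  set.seed(14)
  mat <- matrix(rnorm(40 * 7), 40, 7)
  mat[, 3] <- mat[, 3] + 0.5           # one elevated network
  res <- rm_anova_networks(mat)
  expect_equal(res$F, rm_anova_oracle_F(mat), tolerance = 1e-9)
  expect_gte(res$epsilon, 1 / 6); expect_lte(res$epsilon, 1)
  expect_equal(res$df1, res$epsilon * 6, tolerance = 1e-12)
  expect_equal(res$df2, res$epsilon * 6 * 39, tolerance = 1e-12)
})

test_that("ANOVA degenerate and k = 2 identities", {
  set.seed(15)
  base <- rnorm(10)
  mat <- matrix(base, 10, 4)           # all networks identical per subject
  expect_equal(rm_anova_networks(mat)$F, 0)
  m2 <- cbind(rnorm(12), rnorm(12))
  res <- rm_anova_networks(m2)
  expect_equal(res$epsilon, 1)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)$statistic
  expect_equal(res$F, unname(tt)^2, tolerance = 1e-9)
  expect_error(rm_anova_networks(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("ANOVA is invariant to adding per-subject constants", {
  set.seed(16)
  mat <- matrix(rnorm(25 * 5), 25, 5)
  res1 <- rm_anova_networks(mat)
  res2 <- rm_anova_networks(mat + rnorm(25) * 10)
  expect_equal(res1$F, res2$F, tolerance = 1e-9)
  expect_equal(res1$epsilon, res2$epsilon, tolerance = 1e-9)
})

test_that("post hoc Tukey t-values use the pooled within-subject error", {
  set.seed(17)
  mat <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  mat[, 1] <- mat[, 1] + 1
  res <- rm_anova_networks(mat)
  expect_equal(nrow(res$posthoc), 6L)
  # the elevated column should dominate its comparisons
  ab <- res$posthoc[res$posthoc$a == "a" & res$posthoc$b == "b", ]
  expect_gt(ab$t, 2)
  expect_true(all(res$posthoc$p_adj >= 0 & res$posthoc$p_adj <= 1))
})
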