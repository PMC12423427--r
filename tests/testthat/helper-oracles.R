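# Independent oracles, written from definitions (no calls into the
# package's own statistic paths).

# midranks by explicit counting: rank of x_i = (# strictly smaller) +
# (1 + # tied) / 2
midrank_oracle <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

# Spearman rho = product-moment correlation of midranks, by the raw
# formula (no stats::cor)
spearman_oracle <- function(x, y) {
  rx <- midrank_oracle(x); ry <- midrank_oracle(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# AUC as the exhaustive concordant-pair fraction (ties count 1/2)
auc_pair_oracle <- function(pred_pos, pred_neg) {
  tot <- 0
  for (p in pred_pos) tot <- tot + sum(p > pred_neg) + 0.5 * sum(p == pred_neg)
  tot / (length(pred_pos) * length(pred_neg))
}

# repeated-measures decomposition straight from the definition, by loops
rm_anova_oracle_F <- function(mat) {
  N <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_net <- 0
  for (j in seq_len(k)) ss_net <- ss_net + N * (mean(mat[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(N)) for (j in seq_len(k)) {
    e <- mat[i, j] - mean(mat[i, ]) - mean(mat[, j]) + grand
    ss_err <- ss_err + e^2
  }
  (ss_net / (k - 1)) / (ss_err / ((N - 1) * (k - 1)))
}

# small valid toy scheme: 2 networks x 2 ROIs
toy_scheme <- function() {
  parcellation_scheme(1:4, paste0("r", 1:4),
                      c("FPN", "FPN", "DMN", "DMN"),
                      c("L", "R", "L", "R"))
}

# deterministic small connectome on a given scheme
toy_connectome <- function(scheme, seed = 1) {
  n <- nrow(scheme)
  set.seed(seed)
  sc <- matrix(runif(n * n, 0.01, 0.9), n, n)
  diag(sc) <- 0
  ts <- matrix(rnorm(50 * n), 50, n)
  subject_connectome("toy", sc, fc_from_timeseries(ts), scheme = scheme)
}

# minimal valid cohort table of size n
toy_cohort <- function(n = 20, seed = 1) {
  set.seed(seed)
  pw <- sample(1:3, n, replace = TRUE)
  dw <- sample(0:3, n, replace = TRUE)
  data.frame(subject_id = sprintf("s%03d", 1:n),
             age = rnorm(n, 61, 7),
             sex = sample(c("female", "male"), n, replace = TRUE),
             education = sample(6:16, n, replace = TRUE),
             pwmh = pw, dwmh = dw,
             wmh_volume = rlnorm(n, 0.6, 1.2),
             stringsAsFactors = FALSE)
}
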