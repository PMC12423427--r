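#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: cohort size and
#' demographics matched to the target population (age 61 (7) years, 46.5%
#' female, vascular risk prevalences), a log-normal WMH volume with mean
#' 3.78 mL whose latent burden also drives the Fazekas scores (so severity
#' labels are rule-consistent and the mild fraction is 60.6% in
#' expectation), per-network coupling levels (lowest frontoparietal,
#' highest somatomotor), and standardized generating effects: log-WMH
#' volume on frontoparietal coupling within the mild stratum (0.136),
#' coupling on baseline cognition (0.110), and coupling on follow-up
#' cognition (0.245).
#'
#' @param n_subjects cohort size (default 617).
#' @param n_roi ROIs for connectome generation (default 400).
#' @param network_sizes optional named member counts (see
#'   [default_parcellation()]).
#' @param sparsity fraction of zero SC edges per ROI profile, in (0, 1).
#' @param kappa named per-network coupling knob in `[0, 1]`: the target
#'   Spearman rank agreement between SC and FC edge profiles, which is
#'   also the network's mean coupling level in the fast path.
#' @param beta_wmh_coupling standardized effect of log-WMH volume on the
#'   target network's coupling within the mild stratum.
#' @param beta_coupling_cognition standardized cross-sectional effect of
#'   target-network coupling on the cognition score (mild stratum).
#' @param beta_longitudinal standardized effect of baseline coupling on
#'   the follow-up score (mild stratum), on top of the baseline
#'   autocorrelation.
#' @param beta_age_cognition standardized age effect on cognition.
#' @param coupling_sd between-subject SD of network coupling.
#' @param autocorr within-subject correlation between baseline and
#'   follow-up cognition (an assumption, not an estimate; default 0.6).
#' @param target_network network carrying the generating effects.
#' @param follow_up_fraction fraction of subjects with follow-up data.
#' @param T time-series length when BOLD-like series are requested.
#' @param connectomes also generate per-subject SC/FC matrices and measure
#'   coupling from them (slow; default `FALSE` draws network coupling
#'   directly from the generating linear model).
#' @param log_wmh_effect the generating coupling effect acts on log-WMH
#'   volume (default `TRUE`, matching the log-normal volume model).
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 617L,
                       n_roi = 400L,
                       network_sizes = NULL,
                       sparsity = 0.5,
                       kappa = c(FPN = 0.15, DAN = 0.22, DMN = 0.20,
                                 LMN = 0.18, SMN = 0.32, VAN = 0.25,
                                 VIN = 0.28),
                       beta_wmh_coupling = 0.136,
                       beta_coupling_cognition = 0.110,
                       beta_longitudinal = 0.245,
                       beta_age_cognition = -0.15,
                       coupling_sd = 0.07,
                       autocorr = 0.6,
                       target_network = "FPN",
                       follow_up_fraction = 123 / 617,
                       T = 200L,
                       connectomes = FALSE,
                       log_wmh_effect = TRUE,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (any(kappa < 0 | kappa > 1)) stop("kappa must lie in [0, 1]")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must lie in (0, 1)")
  if (!target_network %in% names(kappa))
    stop("target_network must be one of: ", paste(names(kappa), collapse = ", "))
  if (abs(beta_wmh_coupling) > 1) stop("infeasible beta_wmh_coupling")
  if (beta_coupling_cognition^2 + beta_age_cognition^2 >= 1)
    stop("infeasible cognition effect sizes (implied R^2 >= 1)")
  fu_noise_var <- 1 - (beta_longitudinal^2 + autocorr^2 +
                         2 * beta_longitudinal * autocorr *
                         beta_coupling_cognition)
  if (fu_noise_var <= 0)
    stop("infeasible longitudinal effect sizes (implied R^2 >= 1)")
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_roi = as.integer(n_roi),
    network_sizes = network_sizes, sparsity = sparsity, kappa = kappa,
    beta_wmh_coupling = beta_wmh_coupling,
    beta_coupling_cognition = beta_coupling_cognition,
    beta_longitudinal = beta_longitudinal,
    beta_age_cognition = beta_age_cognition,
    coupling_sd = coupling_sd, autocorr = autocorr,
    target_network = target_network,
    follow_up_fraction = follow_up_fraction, T = as.integer(T),
    connectomes = isTRUE(connectomes), log_wmh_effect = isTRUE(log_wmh_effect),
    # demographic marginals of the emulated population
    age_mean = 61, age_sd = 7, female_p = 0.465,
    education_mean = 9.3, education_sd = 3.8,
    risk_prevalence = c(hypertension = 0.729, diabetes = 0.222,
                        hypercholesterolemia = 0.428, smoking = 0.376,
                        drinking = 0.441),
    # log-normal WMH volume: mean 3.78 mL overall, ~1.10 mild / ~7.91
    # severe once split at the 60.6% quantile of the latent burden
    wmhv_log_sigma = 1.2,
    wmhv_log_mu = log(3.78) - 1.2^2 / 2,
    severity_cut = stats::qnorm(0.606),
    # Fazekas thresholds on the latent burden; dwmh >= 2 exactly above the
    # severity cut and pwmh = 3 only deeper in, so labels obey the rule
    pwmh_cuts = c(1.0, 1.6), dwmh_cuts = c(-0.5, stats::qnorm(0.606), 1.2),
    follow_up_years_mean = 2, follow_up_years_sd = 0.25,
    dsf_mean = 11.9, dsf_sd = 2.7,
    moca_mean = 21.9, moca_sd = 4.7, mmse_mean = 26.3, mmse_sd = 3.3,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# mixture weight on the normal-scores rank signal: for a bivariate normal
# pair with correlation a, the Spearman correlation is (6/pi)*asin(a/2),
# so a = 2*sin(pi*kappa/6) makes the latent rank agreement equal kappa
kappa_to_mixture <- function(kappa) 2 * sin(pi * kappa / 6)

#' Generate a sparse directed structural connectome
#'
#' Per ROI profile: ~(1 - sparsity) * (n - 1) nonzero targets are chosen at
#' random; their weights are drawn log-normal and row-normalized into
#' (0, 1] (rows sum to 1, mimicking tractography connection
#' probabilities). Deterministic given the seed.
#'
#' @param n_roi number of ROIs.
#' @param sparsity fraction of zero edges per profile, in (0, 1).
#' @param seed integer seed.
#' @param min_edges required nonzero edges per profile (error below).
#' @return n_roi x n_roi matrix with zero diagonal.
#' @export
gen_sc <- function(n_roi, sparsity = 0.5, seed, min_edges = 3L) {
  set.seed(seed)
  m <- round((1 - sparsity) * (n_roi - 1))
  if (m < min_edges)
    stop("sparsity ", sparsity, " leaves ", m, " nonzero edges per ",
         "profile; need >= ", min_edges)
  sc <- matrix(0, n_roi, n_roi)
  for (i in seq_len(n_roi)) {
    targets <- sample(setdiff(seq_len(n_roi), i), m)
    w <- stats::rlnorm(m, meanlog = 0, sdlog = 1)
    sc[i, targets] <- w / sum(w)
  }
  sc
}

#' Generate functional connectivity coupled to a structural connectome
#'
#' Builds a symmetric Fisher-z FC matrix whose edge values are a
#' kappa-weighted mixture of the normal scores of the symmetrized SC edge
#' ranks and independent Gaussian noise, rescaled into a plausible z
#' range. Because the rank transform is global and monotone, every ROI
#' profile inherits the target rank agreement: at `kappa = 1` the mixture
#' is noiseless and ROI-wise coupling (on the symmetrized SC profile)
#' equals 1 exactly; at `kappa = 0` its expectation is 0.
#'
#' @param sc structural matrix from [gen_sc()].
#' @param kappa scalar coupling knob in `[0, 1]`, or a named per-network
#'   vector (then `scheme` is required; an edge's mixture weight is the
#'   mean of its endpoints' network weights).
#' @param scheme optional `parcellation_scheme` for per-network kappa.
#' @param seed integer seed.
#' @param timeseries also return a T x n_roi BOLD-like series whose
#'   empirical correlation structure reproduces the FC (exact-correlation
#'   factor construction; requires `T > n_roi`). The returned `fc` is then
#'   recomputed from the series so both are consistent.
#' @param T series length.
#' @return FC matrix, or `list(fc, ts)` when `timeseries = TRUE`.
#' @export
gen_fc <- function(sc, kappa, scheme = NULL, seed, timeseries = FALSE,
                   T = 200L) {
  set.seed(seed + 1L)
  n <- nrow(sc)
  if (length(kappa) > 1L) {
    if (is.null(scheme)) stop("per-network kappa needs a scheme")
    a_roi <- kappa_to_mixture(kappa[scheme$network])
  } else {
    a_roi <- rep(kappa_to_mixture(kappa), n)
  }
  S <- (sc + t(sc)) / 2
  ut <- upper.tri(S)
  nz <- ut & S > 0
  m <- sum(nz)
  tq <- stats::qnorm((rank(S[nz]) - 0.5) / m)
  a_edge <- (outer(a_roi, rep(1, n)) + outer(rep(1, n), a_roi))[nz] / 2
  mix <- a_edge * tq + sqrt(1 - a_edge^2) * stats::rnorm(m)
  fc <- matrix(0, n, n)
  fc[nz] <- 0.25 + 0.15 * mix
  z0 <- ut & S == 0
  fc[z0] <- 0.25 + 0.15 * stats::rnorm(sum(z0))
  fc <- fc + t(fc)
  diag(fc) <- 0
  if (!timeseries) return(fc)
  if (T <= n) stop("need T > n_roi (", n, ") for the factor construction")
  C <- tanh(fc)
  diag(C) <- 1
  # project to the nearest admissible correlation by eigenvalue clipping
  ev <- eigen(C, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6)
  C <- ev$vectors %*% (lam * t(ev$vectors))
  C <- stats::cov2cor(C)
  # whitened factors give the target correlation exactly in-sample
  Z <- matrix(stats::rnorm(T * n), T, n)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Zw <- Z %*% backsolve(chol(stats::cov(Z)), diag(n))
  ts <- Zw %*% chol(C)
  ts <- sweep(ts, 2, 100, `+`)  # arbitrary BOLD-like baseline
  list(fc = fc_from_timeseries(ts), ts = ts)
}

#' Generate a linked synthetic cohort
#'
#' Draws demographics, a latent WMH burden that produces both the
#' log-normal WMH volume and rule-consistent Fazekas scores, network
#' coupling values carrying the configured standardized effects, and
#' baseline plus follow-up cognition. With `connectomes = TRUE` in the
#' config, per-subject SC/FC matrices are generated with per-subject
#' coupling knobs and the coupling table is measured from them with
#' [cohort_coupling()]; otherwise coupling is drawn directly from the
#' generating linear model (fast path).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `cohort` (data.frame), `coupling`
#'   (long data.frame as from [cohort_coupling()]), `scheme`,
#'   `connectomes` (list or `NULL`), `config`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  id <- sprintf("sub%04d", seq_len(n))
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$female_p, "female", "male")
  education <- pmax(0, round(stats::rnorm(n, cfg$education_mean,
                                          cfg$education_sd)))
  risks <- lapply(cfg$risk_prevalence,
                  function(p) as.integer(stats::runif(n) < p))
  L <- stats::rnorm(n)                      # latent WMH burden
  wmh_volume <- exp(cfg$wmhv_log_mu + cfg$wmhv_log_sigma * L)
  pwmh <- 1L + (L > cfg$pwmh_cuts[1]) + (L > cfg$pwmh_cuts[2])
  dwmh <- (L > cfg$dwmh_cuts[1]) + (L > cfg$dwmh_cuts[2]) +
    (L > cfg$dwmh_cuts[3])
  severity <- classify_severity(pwmh, dwmh)
  mild <- severity == "mild"
  log_wmh <- log(wmh_volume)

  cohort <- data.frame(subject_id = id, age = age, sex = sex,
                       education = education, stringsAsFactors = FALSE)
  for (rf in names(risks)) cohort[[rf]] <- risks[[rf]]
  cohort$pwmh <- pwmh; cohort$dwmh <- dwmh
  cohort$wmh_volume <- wmh_volume; cohort$log_wmh <- log_wmh
  cohort$severity <- severity

  nets <- names(cfg$kappa)
  # standardized burden within each stratum drives the target-network effect
  zL <- numeric(n)
  zL[mild] <- as.numeric(scale(log_wmh[mild]))
  zL[!mild] <- as.numeric(scale(log_wmh[!mild]))
  bwc <- cfg$beta_wmh_coupling

  if (cfg$connectomes) {
    scheme <- default_parcellation(cfg$n_roi, cfg$network_sizes)
    kap <- cfg$kappa
    conns <- vector("list", n)
    for (s in seq_len(n)) {
      ks <- kap
      tgt <- cfg$target_network
      eff <- if (mild[s]) bwc * zL[s] else 0
      ks[tgt] <- min(max(cfg$kappa[tgt] + cfg$coupling_sd *
                           (eff + stats::rnorm(1) * sqrt(max(0, 1 - bwc^2))),
                         0), 1)
      sseed <- cfg$seed * 1000L + s
      sc <- gen_sc(cfg$n_roi, cfg$sparsity, seed = sseed)
      fc <- gen_fc(sc, ks, scheme = scheme, seed = sseed)
      conns[[s]] <- subject_connectome(id[s], sc, fc, scheme = scheme)
    }
    coupling <- cohort_coupling(conns, scheme, sc_mode = "symmetrized")
  } else {
    scheme <- NULL; conns <- NULL
    eps <- matrix(stats::rnorm(n * length(nets)), n, length(nets),
                  dimnames = list(NULL, nets))
    tgt <- cfg$target_network
    eps[mild, tgt] <- bwc * zL[mild] +
      sqrt(1 - bwc^2) * eps[mild, tgt]
    vals <- sweep(cfg$coupling_sd * eps, 2, cfg$kappa[nets], `+`)
    coupling <- data.frame(
      subject_id = rep(id, each = length(nets)),
      network = rep(nets, times = n),
      rho = as.vector(t(vals)),
      n_rois_defined = NA_integer_, stringsAsFactors = FALSE)
  }

  # cognition: standardized generating model on the target-network coupling
  cw <- coupling[coupling$network == cfg$target_network, ]
  cvec <- cw$rho[match(id, cw$subject_id)]
  zx <- numeric(n)
  zx[mild] <- as.numeric(scale(cvec[mild]))
  zx[!mild] <- as.numeric(scale(cvec[!mild]))
  zage <- as.numeric(scale(age))
  bcc <- cfg$beta_coupling_cognition; bage <- cfg$beta_age_cognition
  yz <- numeric(n)
  yz[mild] <- bcc * zx[mild] + bage * zage[mild] +
    sqrt(1 - bcc^2 - bage^2) * stats::rnorm(sum(mild))
  yz[!mild] <- bage * zage[!mild] +
    sqrt(1 - bage^2) * stats::rnorm(sum(!mild))
  cohort$digit_span_forward <- cfg$dsf_mean + cfg$dsf_sd * yz
  gz <- function() bage * zage - 0.1 * L +
    sqrt(1 - bage^2 - 0.01) * stats::rnorm(n)
  cohort$moca <- cfg$moca_mean + cfg$moca_sd * gz()
  cohort$mmse <- cfg$mmse_mean + cfg$mmse_sd * gz()

  # follow-up subset with autocorrelated outcome and the longitudinal effect
  n_fu <- round(cfg$follow_up_fraction * n)
  fu_idx <- sort(sample(seq_len(n), n_fu))
  isfu <- seq_len(n) %in% fu_idx
  cohort$follow_up <- isfu
  cohort$follow_up_duration <- ifelse(
    isfu, stats::rnorm(n, cfg$follow_up_years_mean, cfg$follow_up_years_sd),
    NA_real_)
  blong <- cfg$beta_longitudinal; a <- cfg$autocorr
  fuz <- rep(NA_real_, n)
  for (grp in list(which(mild & isfu), which(!mild & isfu))) {
    if (!length(grp)) next
    bx <- if (all(mild[grp])) blong else 0
    cov_xy <- if (all(mild[grp])) bcc else 0
    nv <- 1 - (bx^2 + a^2 + 2 * bx * a * cov_xy)
    fuz[grp] <- bx * zx[grp] + a * yz[grp] +
      sqrt(max(nv, 1e-8)) * stats::rnorm(length(grp))
  }
  cohort$digit_span_forward_fu <- ifelse(
    isfu, cfg$dsf_mean + cfg$dsf_sd * fuz, NA_real_)

  structure(list(cohort = cohort, coupling = coupling, scheme = scheme,
                 connectomes = conns, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated bundle in the pipeline's file layout
#'
#' Emits `scheme.tsv` (when connectomes were generated), `cohort.csv`,
#' `coupling.csv`, per-subject matrix directories, and `manifest.json`
#' (config, seed, package version, file digests).
#'
#' @param sim a `sim_cohort` from [gen_cohort()].
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  write_results(sim$coupling, file.path(dir, "coupling.csv"),
                overwrite = TRUE)
  if (!is.null(sim$scheme))
    write_parcellation(sim$scheme, file.path(dir, "scheme.tsv"))
  if (!is.null(sim$connectomes))
    for (cx in sim$connectomes)
      write_connectome(cx, file.path(dir, "subjects", cx$subject_id))
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  manifest <- run_manifest(sim$config, seeds = sim$config$seed,
                           inputs = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
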