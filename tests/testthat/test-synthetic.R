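test_that("generated SC is sparse, row-normalized and reproducible", {
  sc <- gen_sc(20, sparsity = 0.5, seed = 3)
  expect_equal(diag(sc), rep(0, 20))
  nz <- rowSums(sc > 0)
  expect_true(all(nz %in% 9:10))
  expect_equal(unname(rowSums(sc)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, gen_sc(20, sparsity = 0.5, seed = 3))
  expect_error(gen_sc(6, sparsity = 0.9, seed = 1), "nonzero edges")
})

test_that("SC weights are log-normal in shape (row-centered logs)", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  sc <- gen_sc(1000, sparsity = 0.5, seed = 4)
  logs <- unlist(lapply(seq_len(1000), function(i) {
    w <- sc[i, sc[i, ] > 0]
    log(w) - mean(log(w))
  }))
  expect_lt(abs(skew(logs)), 0.1)
})

test_that("coupling knob is calibrated: exact at 1, null at 0, monotone", {
  sch <- default_parcellation(60)
  sc <- gen_sc(60, 0.5, seed = 7)
  fc1 <- gen_fc(sc, kappa = 1, seed = 7)
  cx <- subject_connectome("s", sc, fc1, scheme = sch)
  prof <- subject_coupling(cx, sch, sc_mode = "symmetrized")
  expect_equal(prof$roi_rho, rep(1, 60))
  # kappa = 0: mean coupling near zero over 100 subjects
  rh0 <- vapply(1:100, function(s) {
    scx <- gen_sc(30, 0.5, seed = 100 + s)
    fcx <- gen_fc(scx, kappa = 0, seed = 100 + s)
    cxx <- subject_connectome("x", scx, fcx,
                              scheme = default_parcellation(30))
    mean(subject_coupling(cxx, default_parcellation(30),
                          sc_mode = "symmetrized")$network_rho$rho)
  }, numeric(1))
  expect_lt(abs(mean(rh0)), 0.05)
})

test_that("generated connectomes satisfy the module invariants unchanged", {
  sch <- default_parcellation(40)
  sc <- gen_sc(40, 0.6, seed = 9)
  fc <- gen_fc(sc, kappa = 0.5, seed = 9)
  expect_silent(cx <- subject_connectome("g", sc, fc, scheme = sch))
  expect_equal(fc, t(fc))
  # time-series expansion reproduces its own fc through the standard path
  out <- gen_fc(gen_sc(15, 0.5, seed = 10), 0.6, seed = 10,
                timeseries = TRUE, T = 50)
  expect_equal(dim(out$ts), c(50L, 15L))
  expect_equal(fc_from_timeseries(out$ts), out$fc, tolerance = 1e-9)
  expect_error(gen_fc(gen_sc(15, 0.5, seed = 10), 0.6, seed = 10,
                      timeseries = TRUE, T = 12), "T > n_roi")
})

test_that("cohort marginals match the emulated population", {
  sim <- gen_cohort(sim_config(seed = 20))
  co <- sim$cohort
  expect_equal(nrow(co), 617L)
  frac_mild <- mean(co$severity == "mild")
  expect_gt(frac_mild, 0.55); expect_lt(frac_mild, 0.66)
  expect_gt(mean(co$wmh_volume), 2.5); expect_lt(mean(co$wmh_volume), 5.5)
  expect_gt(mean(co$sex == "female"), 0.40)
  expect_lt(mean(co$sex == "female"), 0.53)
  # severity labels are rule-consistent by construction
  expect_equal(co$severity, classify_severity(co$pwmh, co$dwmh))
  expect_equal(sum(co$follow_up), 123L)
  expect_true(all(is.na(co$digit_span_forward_fu[!co$follow_up])))
})

test_that("generation is deterministic from the seed (byte-identical CSV)", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 40, seed = 33)
  write_simulation(gen_cohort(cfg), d1)
  write_simulation(gen_cohort(cfg), d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  expect_identical(readLines(file.path(d1, "coupling.csv")),
                   readLines(file.path(d2, "coupling.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("null effects center the estimated betas on zero", {
  est <- vapply(1:60, function(s) {
    sim <- gen_cohort(sim_config(n_subjects = 200,
                                 beta_wmh_coupling = 0,
                                 beta_coupling_cognition = 0,
                                 beta_longitudinal = 0, seed = s))
    cw <- sim$coupling[sim$coupling$network == "FPN", ]
    tab <- sim$cohort
    tab$rho_FPN <- cw$rho[match(tab$subject_id, cw$subject_id)]
    mild <- tab[tab$severity == "mild", ]
    linear_assoc(mild, "rho_FPN", "log_wmh",
                 covariate_sets("wmh_coupling"))$beta_std
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.02)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = 1, beta_coupling_cognition = 0.9,
                          beta_age_cognition = -0.9), "R\\^2")
  expect_error(sim_config(seed = 1, beta_longitudinal = 0.9,
                          autocorr = 0.9), "longitudinal")
  expect_error(sim_config(seed = 1, kappa = c(FPN = 1.2)), "kappa")
  expect_error(sim_config(seed = 1, sparsity = 1), "sparsity")
  expect_error(sim_config(n_subjects = 10), "seed")
})

test_that("connectome mode measures coupling from generated matrices", {
  cfg <- sim_config(n_subjects = 12, n_roi = 60, connectomes = TRUE,
                    seed = 41)
  sim <- gen_cohort(cfg)
  expect_length(sim$connectomes, 12L)
  expect_equal(nrow(sim$coupling), 12L * 7L)
  expect_false(any(is.na(sim$coupling$rho)))
  # measured network coupling tracks the per-network kappa profile
  agg <- tapply(sim$coupling$rho, sim$coupling$network, mean)
  expect_gt(cor(agg[names(cfg$kappa)], cfg$kappa, method = "spearman"),
            0.7)
})
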