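test_that("monotone agreement and reversal hit the bounds", {
  expect_equal(roi_coupling(c(0.1, 0.2, 0.3), c(0.5, 1.1, 2.0))$rho, 1)
  expect_equal(roi_coupling(c(0.1, 0.2, 0.3), c(2.0, 1.1, 0.5))$rho, -1)
})

test_that("insufficient or constant selections give the undefined sentinel", {
  r <- roi_coupling(c(0.4, 0, 0), c(1, 2, 3), min_edges = 3)
  expect_true(is.na(r$rho))
  expect_equal(r$n_edges, 1L)
  r2 <- roi_coupling(c(0.2, 0.2, 0.2, 0.2), c(1, 2, 3, 4))
  expect_true(is.na(r2$rho))   # constant SC selection
  expect_error(roi_coupling(1:3, 1:4), "lengths differ")
})

test_that("edge-selection policies differ only on exact-zero FC", {
  sc <- c(0.1, 0.5, 0.3, 0.2)
  fc <- c(0.4, 0, 0.2, 0.9)
  a <- roi_coupling(sc, fc, policy = "sc_nonzero")
  b <- roi_coupling(sc, fc, policy = "both_nonzero")
  expect_equal(a$n_edges, 4L)
  expect_equal(b$n_edges, 3L)
})

test_that("rho equals the brute-force midrank oracle on tied profiles", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)  # many ties
    fc <- sample(seq(-0.3, 1.2, by = 0.15), n, replace = TRUE)
    if (length(unique(sc)) < 2 || length(unique(fc)) < 2) next
    got <- roi_coupling(sc, fc, min_edges = 3)$rho
    worst <- max(worst, abs(got - spearman_oracle(sc, fc)))
  }
  expect_lt(worst, 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(13)
  for (i in 1:30) {
    sc <- runif(10, 0.01, 1)
    fc <- rnorm(10)
    base <- roi_coupling(sc, fc)$rho
    fmap <- sample(list(function(x) exp(x), function(x) x^3,
                        function(x) atan(x) * 5 + 2), 1)[[1]]
    expect_equal(roi_coupling(sc, fmap(fc))$rho, base, tolerance = 1e-12)
    # monotone map on SC that preserves positivity (selection unchanged)
    expect_equal(roi_coupling(sc^2, fc)$rho, base, tolerance = 1e-12)
  }
})

test_that("an 8-ROI toy matches hand-computed ranks", {
  # ROI 1 profile over targets 2..8; sc has one zero (dropped)
  sc <- c(0.5, 0.1, 0, 0.3, 0.2, 0.4, 0.1)
  fc <- c(0.9, 0.2, 5.0, 0.6, 0.1, 0.7, 0.3)
  # selected: indices 1,2,4,5,6,7 -> sc ranks 6, 1.5, 4, 3, 5, 1.5
  #                                  fc ranks 6, 2, 4, 1, 5, 3
  rx <- c(6, 1.5, 4, 3, 5, 1.5); ry <- c(6, 2, 4, 1, 5, 3)
  expected <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(roi_coupling(sc, fc)$rho, expected, tolerance = 1e-12)
})

test_that("subject coupling: monotone FC link gives all rho = 1", {
  sch <- toy_scheme()
  set.seed(3)
  sc <- matrix(runif(16, 0.05, 0.9), 4, 4); diag(sc) <- 0
  sc <- (sc + t(sc)) / 2                       # symmetric so fc can follow
  fc <- log1p(sc); diag(fc) <- 0               # strictly increasing in sc
  cx <- subject_connectome("m", sc, fc, scheme = sch)
  prof <- subject_coupling(cx, sch)
  expect_equal(prof$roi_rho, rep(1, 4))
  expect_equal(prof$network_rho$rho, c(1, 1))
})

test_that("network rho averages defined members and is bounded by them", {
  sch <- parcellation_scheme(1:6, paste0("r", 1:6),
                             rep(c("FPN", "DMN"), each = 3),
                             rep("L", 6))
  cx <- toy_connectome(sch, seed = 21)
  prof <- subject_coupling(cx, sch)
  for (nt in c("FPN", "DMN")) {
    rr <- prof$roi_rho[network_members(sch, nt)]
    rr <- rr[!is.na(rr)]
    got <- prof$network_rho$rho[prof$network_rho$network == nt]
    expect_equal(got, mean(rr), tolerance = 1e-12)
    expect_gte(got, min(rr)); expect_lte(got, max(rr))
  }
})

test_that("FC independent of SC gives near-zero mean network coupling", {
  sch <- toy_scheme()
  set.seed(44)
  rhos <- replicate(100, {
    sc <- matrix(runif(16, 0.05, 0.9), 4, 4); diag(sc) <- 0
    fc <- matrix(0, 4, 4)
    v <- rnorm(6); fc[upper.tri(fc)] <- v
    fc <- fc + t(fc)
    prof <- subject_coupling(subject_connectome("x", sc, fc, scheme = sch),
                             sch)
    mean(prof$network_rho$rho)
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("cohort coupling table is deterministic and long-format", {
  sch <- toy_scheme()
  cxs <- lapply(1:3, function(i) toy_connectome(sch, seed = i))
  for (i in 1:3) cxs[[i]]$subject_id <- sprintf("s%d", 4 - i)  # unsorted ids
  tab <- cohort_coupling(cxs, sch)
  expect_equal(nrow(tab), 6L)  # 3 subjects x 2 networks
  expect_equal(tab$subject_id, rep(c("s1", "s2", "s3"), each = 2))
  tab2 <- cohort_coupling(rev(cxs), sch)
  expect_equal(tab, tab2)      # input order is irrelevant
  cxs[[2]]$subject_id <- "s1"
  expect_error(cohort_coupling(cxs, sch), "duplicate")
})
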