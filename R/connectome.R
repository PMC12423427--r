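#' Functional connectivity from ROI time series
#'
#' Correlates every ROI's time course with every other ROI's (Pearson),
#' then applies Fisher's z-transform, `z = atanh(r)`. To keep perfectly
#' collinear columns finite, `|r|` is clamped to `1 - 1e-7` before the
#' transform. The diagonal is set to 0 and is never consumed by any
#' downstream computation.
#'
#' @param ts T x n_roi numeric matrix (T >= 3 frames); every column must be
#'   nonconstant.
#' @return n_roi x n_roi symmetric Fisher-z matrix with zero diagonal.
#' @export
fc_from_timeseries <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("ts must be a numeric matrix")
  if (nrow(ts) < 3L) stop("need at least 3 time points, got ", nrow(ts))
  if (!all(is.finite(ts))) stop("ts contains non-finite values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time series for ROI(s): ",
         paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z <- (z + t(z)) / 2          # exact symmetry against rounding
  diag(z) <- 0
  z
}

#' Normalize streamline counts to connection probabilities
#'
#' Tractography edge weights: the probability of connection from seed ROI i
#' to target ROI j is the number of streamlines from i reaching j divided
#' by the total number of streamlines sampled from i (e.g. 5000 per seed
#' voxel times the voxel count).
#'
#' @param counts n_roi x n_roi nonnegative integer matrix of streamline
#'   counts; row i = seed ROI i.
#' @param samples_per_seed positive integer vector, streamlines sampled per
#'   seed ROI (recycled if scalar).
#' @return n_roi x n_roi probability matrix in `[0, 1]`, zero diagonal.
#' @export
normalize_sc <- function(counts, samples_per_seed) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (any(counts < 0)) stop("negative streamline counts")
  n <- nrow(counts)
  samples_per_seed <- rep_len(as.numeric(samples_per_seed), n)
  if (any(samples_per_seed <= 0)) stop("samples_per_seed must be positive")
  if (any(counts > samples_per_seed))
    stop("streamline counts exceed samples sampled from their seed")
  sc <- counts / samples_per_seed
  diag(sc) <- 0
  sc
}

#' Within-network SC and FC summaries
#'
#' Within-network structural connectivity is the mean weight `w_ij` over
#' ordered off-diagonal ROI pairs inside each network (equivalent to the
#' mean of the symmetrized matrix, so no information is lost by keeping SC
#' directed); within-network functional connectivity is the mean Fisher-z
#' over unordered off-diagonal pairs.
#'
#' @param connectome a `subject_connectome` with `fc` present.
#' @param scheme a `parcellation_scheme`.
#' @return data.frame with columns `network`, `n_roi`, `within_sc`,
#'   `within_fc`. Networks with fewer than 2 ROIs yield `NA` with a
#'   warning.
#' @export
within_network_summaries <- function(connectome, scheme) {
  stopifnot(inherits(connectome, "subject_connectome"),
            inherits(scheme, "parcellation_scheme"))
  if (is.null(connectome$fc)) stop("connectome has no fc")
  nets <- networks(scheme)
  out <- data.frame(network = nets, n_roi = NA_integer_,
                    within_sc = NA_real_, within_fc = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(nets)) {
    idx <- network_members(scheme, nets[k])
    out$n_roi[k] <- length(idx)
    if (length(idx) < 2L) {
      warning("network ", nets[k], " has < 2 ROIs; summaries undefined")
      next
    }
    scb <- connectome$sc[idx, idx, drop = FALSE]
    fcb <- connectome$fc[idx, idx, drop = FALSE]
    off <- row(scb) != col(scb)
    out$within_sc[k] <- mean(scb[off])
    out$within_fc[k] <- mean(fcb[upper.tri(fcb)])
  }
  out
}

#' Head-motion quality control
#'
#' A subject fails if mean Power framewise displacement exceeds
#' `fd_threshold` (default 0.5 mm) or any of the six rigid-body motion
#' parameters (3 translations in mm, 3 rotations in degrees) exceeds
#' `motion_threshold` (default 3). Both thresholds are strict: a value
#' exactly at the threshold passes.
#'
#' @param motion data.frame with columns `subject_id`, `mean_fd`, `tx`,
#'   `ty`, `tz`, `rx`, `ry`, `rz` (maximum absolute excursion per
#'   parameter), or a single-row list with those fields.
#' @param fd_threshold mean-FD exclusion threshold in mm.
#' @param motion_threshold per-parameter exclusion threshold in mm/degrees.
#' @return data.frame with `subject_id`, `pass` (logical), `reason`
#'   (`NA` when passing).
#' @export
motion_qc <- function(motion, fd_threshold = 0.5, motion_threshold = 3) {
  motion <- as.data.frame(motion, stringsAsFactors = FALSE)
  pars <- c("tx", "ty", "tz", "rx", "ry", "rz")
  need <- c("subject_id", "mean_fd", pars)
  miss <- setdiff(need, names(motion))
  if (length(miss)) stop("motion table missing: ", paste(miss, collapse = ", "))
  vals <- as.matrix(motion[, c("mean_fd", pars)])
  if (any(vals < 0)) stop("motion summaries must be nonnegative")
  fail_fd <- motion$mean_fd > fd_threshold
  fail_mot <- apply(as.matrix(motion[, pars]) > motion_threshold, 1, any)
  reason <- rep(NA_character_, nrow(motion))
  reason[fail_mot] <- paste0("motion parameter > ", motion_threshold)
  reason[fail_fd] <- paste0("mean FD > ", fd_threshold)  # FD reported first
  data.frame(subject_id = motion$subject_id,
             pass = !(fail_fd | fail_mot),
             reason = reason, stringsAsFactors = FALSE)
}
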