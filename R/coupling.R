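#' ROI-wise structure-function coupling
#'
#' The core statistic: for one ROI, the Spearman rank correlation between
#' its structural connectivity profile (edge weights to every other ROI)
#' and its functional connectivity profile (Fisher-z values to the same
#' ROIs), computed over the selected (nonzero) edges. Ties receive
#' midranks. The result is the undefined sentinel `NA` when fewer than
#' `min_edges` edges survive selection or either selected vector is
#' constant; undefined values propagate as `NA`, never as zeros.
#'
#' @param sc_profile numeric vector of structural weights for one ROI,
#'   self-edge excluded.
#' @param fc_profile numeric vector of Fisher-z values, aligned with
#'   `sc_profile` by target ROI.
#' @param policy edge selection: `"sc_nonzero"` (default) keeps edges with
#'   SC > 0; `"both_nonzero"` additionally requires FC != 0. FC is
#'   continuous so the default avoids seed-dependent selection on exact
#'   zeros.
#' @param min_edges minimum selected edges for a defined correlation
#'   (default 3; Spearman is degenerate below that).
#' @return list with `rho` (Spearman rho or `NA`) and `n_edges` (edges
#'   entering the correlation).
#' @export
roi_coupling <- function(sc_profile, fc_profile,
                         policy = c("sc_nonzero", "both_nonzero"),
                         min_edges = 3L) {
  policy <- match.arg(policy)
  if (length(sc_profile) != length(fc_profile))
    stop("sc_profile and fc_profile lengths differ (",
         length(sc_profile), " vs ", length(fc_profile), ")")
  keep <- sc_profile > 0
  if (policy == "both_nonzero") keep <- keep & fc_profile != 0
  keep <- keep & is.finite(sc_profile) & is.finite(fc_profile)
  x <- sc_profile[keep]; y <- fc_profile[keep]
  n <- length(x)
  if (n < min_edges || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, n_edges = n))
  list(rho = stats::cor(x, y, method = "spearman"), n_edges = n)
}

#' Subject-level coupling profile
#'
#' Computes ROI-wise coupling for every ROI and aggregates to network
#' coupling: the mean of the defined member ROIs' rho values (undefined
#' ROIs are dropped from the mean, not zero-filled).
#'
#' @param connectome a `subject_connectome` with both `sc` and `fc`.
#' @param scheme a `parcellation_scheme`.
#' @param policy edge-selection policy, see [roi_coupling()].
#' @param sc_mode `"directed"` (default) uses the ROI's outgoing weights
#'   (row i of SC, matching the seed-region framing of probabilistic
#'   tractography); `"symmetrized"` uses `(w_ij + w_ji) / 2`.
#' @param min_edges minimum edges per defined ROI correlation.
#' @return object of class `coupling_profile`: list with `subject_id`,
#'   `roi_rho` (length n_roi), `n_edges_used`, and `network_rho`
#'   (data.frame: `network`, `rho`, `n_rois_defined`).
#' @export
subject_coupling <- function(connectome, scheme,
                             policy = c("sc_nonzero", "both_nonzero"),
                             sc_mode = c("directed", "symmetrized"),
                             min_edges = 3L) {
  stopifnot(inherits(connectome, "subject_connectome"),
            inherits(scheme, "parcellation_scheme"))
  policy <- match.arg(policy)
  sc_mode <- match.arg(sc_mode)
  if (is.null(connectome$fc)) stop("connectome has no fc; build it first")
  sc <- connectome$sc
  if (sc_mode == "symmetrized") sc <- (sc + t(sc)) / 2
  fc <- connectome$fc
  n <- nrow(sc)
  roi_rho <- rep(NA_real_, n)
  n_edges <- integer(n)
  for (i in seq_len(n)) {
    res <- roi_coupling(sc[i, -i], fc[i, -i], policy = policy,
                        min_edges = min_edges)
    roi_rho[i] <- res$rho
    n_edges[i] <- res$n_edges
  }
  nets <- networks(scheme)
  net_rho <- data.frame(network = nets, rho = NA_real_,
                        n_rois_defined = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(nets)) {
    rr <- roi_rho[network_members(scheme, nets[k])]
    def <- rr[!is.na(rr)]
    net_rho$n_rois_defined[k] <- length(def)
    if (length(def) == 0L) {
      warning("network ", nets[k], " has no defined ROI coupling for ",
              connectome$subject_id)
    } else {
      net_rho$rho[k] <- mean(def)
    }
  }
  structure(list(subject_id = connectome$subject_id, roi_rho = roi_rho,
                 n_edges_used = n_edges, network_rho = net_rho),
            class = "coupling_profile")
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat("Coupling profile for", x$subject_id, "-",
      sum(!is.na(x$roi_rho)), "of", length(x$roi_rho), "ROIs defined\n")
  print(x$network_rho)
  invisible(x)
}

#' Cohort-level network coupling table
#'
#' Batch wrapper: one row per (subject, network), deterministically ordered
#' by subject id then network label order of the scheme.
#'
#' @param connectomes list of `subject_connectome` objects.
#' @param scheme a `parcellation_scheme`.
#' @param ... passed to [subject_coupling()].
#' @return long-format data.frame: `subject_id`, `network`, `rho`,
#'   `n_rois_defined`.
#' @export
cohort_coupling <- function(connectomes, scheme, ...) {
  if (length(connectomes) == 0L) stop("need at least one connectome")
  ids <- vapply(connectomes, function(x) x$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  rows <- lapply(connectomes[order(ids)], function(cx) {
    prof <- subject_coupling(cx, scheme, ...)
    cbind(subject_id = cx$subject_id, prof$network_rho,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
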