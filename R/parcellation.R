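#' @title Cortical parcellation schemes
#' @name parcellation
#' @description A parcellation scheme assigns every region of interest (ROI)
#'   of a cortical parcellation to exactly one resting-state network. The
#'   default layout follows the 400-parcel scheme whose parcels group into
#'   seven canonical networks: frontoparietal (FPN), dorsal attention (DAN),
#'   default mode (DMN), limbic (LMN), somatomotor (SMN), ventral attention
#'   (VAN) and visual (VIN).
NULL

#' Canonical seven-network labels
#' @keywords internal
CANONICAL_NETWORKS <- c("FPN", "DAN", "DMN", "LMN", "SMN", "VAN", "VIN")

#' Construct and validate a parcellation scheme
#'
#' @param roi_id integer ROI labels, 1-based and contiguous.
#' @param roi_name character ROI names.
#' @param network network label per ROI; every label must belong to
#'   `networks` and every network must have at least two member ROIs.
#' @param hemisphere `"L"` or `"R"` per ROI.
#' @param networks closed set of admissible network labels. Defaults to the
#'   seven canonical resting-state networks.
#' @return An object of class `parcellation_scheme`: a data.frame with
#'   columns `roi_id`, `roi_name`, `network`, `hemisphere`, ordered by
#'   `roi_id`.
#' @examples
#' sch <- parcellation_scheme(1:4, paste0("roi", 1:4),
#'                            c("FPN", "FPN", "DMN", "DMN"),
#'                            c("L", "R", "L", "R"))
#' networks(sch)
#' @export
parcellation_scheme <- function(roi_id, roi_name, network, hemisphere,
                                networks = CANONICAL_NETWORKS) {
  roi_id <- as.integer(roi_id)
  network <- trimws(as.character(network))
  hemisphere <- trimws(as.character(hemisphere))
  n <- length(roi_id)
  if (length(roi_name) != n || length(network) != n || length(hemisphere) != n)
    stop("roi_name, network and hemisphere must match roi_id in length")
  if (anyNA(roi_id)) stop("roi_id must be integer and non-missing")
  if (anyDuplicated(roi_id))
    stop("duplicate roi_id: ", paste(roi_id[duplicated(roi_id)], collapse = ", "))
  scheme <- data.frame(roi_id = roi_id, roi_name = as.character(roi_name),
                       network = network, hemisphere = hemisphere,
                       stringsAsFactors = FALSE)
  scheme <- scheme[order(scheme$roi_id), , drop = FALSE]
  rownames(scheme) <- NULL
  if (!identical(scheme$roi_id, seq_len(n)))
    stop("roi_id must be contiguous 1..", n, "; missing: ",
         paste(setdiff(seq_len(n), scheme$roi_id), collapse = ", "))
  bad <- !scheme$network %in% networks
  if (any(bad))
    stop("unknown network label in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(scheme$network[bad]), collapse = ", "))
  if (!all(scheme$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  sizes <- table(scheme$network)
  if (any(sizes < 2))
    stop("every network needs >= 2 member ROIs; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  attr(scheme, "networks") <- intersect(networks, scheme$network)
  class(scheme) <- c("parcellation_scheme", "data.frame")
  scheme
}

#' Read a parcellation lookup table
#'
#' Reads a tab- or comma-delimited table with columns `roi_id`, `roi_name`,
#' `network`, `hemisphere` (header required). Whitespace around labels is
#' normalized away before validation.
#'
#' @param path path to the lookup table.
#' @param networks admissible network labels (see [parcellation_scheme()]).
#' @return a `parcellation_scheme`.
#' @export
read_parcellation <- function(path, networks = CANONICAL_NETWORKS) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           quote = "\"", comment.char = "")
  need <- c("roi_id", "roi_name", "network", "hemisphere")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parcellation table missing column(s): ", paste(miss, collapse = ", "))
  parcellation_scheme(tab$roi_id, tab$roi_name, tab$network, tab$hemisphere,
                      networks = networks)
}

#' Write a parcellation scheme to a lookup table
#' @param scheme a `parcellation_scheme`.
#' @param path output path; tab-delimited with header.
#' @export
write_parcellation <- function(scheme, path) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  utils::write.table(as.data.frame(scheme)[, c("roi_id", "roi_name",
                                               "network", "hemisphere")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic parcellation
#'
#' Builds a scheme with the canonical seven networks and configurable
#' membership counts. This stands in for a real atlas lookup table (which is
#' user-supplied, not vendored): ROI order and network sizes are plausible
#' but the assignment is synthetic.
#'
#' @param n_roi total number of ROIs (default 400).
#' @param network_sizes named integer vector of member counts per network;
#'   must sum to `n_roi`. Default splits `n_roi` across the seven canonical
#'   networks roughly proportionally to their cortical extent.
#' @return a `parcellation_scheme`.
#' @export
default_parcellation <- function(n_roi = 400L, network_sizes = NULL) {
  n_roi <- as.integer(n_roi)
  if (is.null(network_sizes)) {
    # approximate relative extents of the seven networks
    prop <- c(FPN = 0.13, DAN = 0.12, DMN = 0.23, LMN = 0.07,
              SMN = 0.18, VAN = 0.12, VIN = 0.15)
    network_sizes <- pmax(2L, as.integer(round(prop * n_roi)))
    names(network_sizes) <- names(prop)
    # fix rounding drift on the largest network
    network_sizes[["DMN"]] <- network_sizes[["DMN"]] + n_roi - sum(network_sizes)
  }
  if (sum(network_sizes) != n_roi)
    stop("network_sizes must sum to n_roi")
  labs <- rep(names(network_sizes), times = network_sizes)
  hemi <- rep(c("L", "R"), length.out = n_roi)
  parcellation_scheme(seq_len(n_roi), sprintf("%s_%03d", labs, seq_len(n_roi)),
                      labs, hemi, networks = names(network_sizes))
}

#' Network labels of a scheme
#' @param scheme a `parcellation_scheme`.
#' @return character vector of network labels in scheme order.
#' @export
networks <- function(scheme) attr(scheme, "networks")

#' Member ROI indices of one network
#' @param scheme a `parcellation_scheme`.
#' @param network a network label.
#' @return integer vector of ROI indices.
#' @export
network_members <- function(scheme, network) {
  which(scheme$network == network)
}

#' @export
print.parcellation_scheme <- function(x, ...) {
  cat("Parcellation scheme:", nrow(x), "ROIs,",
      length(networks(x)), "networks\n")
  print(table(x$network))
  invisible(x)
}
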