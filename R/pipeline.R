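#' Run manifest
#'
#' Records everything needed to reproduce a run: a hash of the
#' configuration, digests of the input files, the package version, seeds
#' and a timestamp. Identical manifests imply identical outputs for the
#' deterministic stages.
#'
#' @param config a configuration list (serialized to JSON for hashing).
#' @param seeds integer seeds used.
#' @param inputs character vector of input file paths (digested with md5).
#' @return named list.
#' @export
run_manifest <- function(config, seeds = integer(), inputs = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.character(d), basename(names(d)))
  } else NULL
  list(config_hash = as.character(tools::md5sum(tmp)),
       input_digests = as.list(digests),
       package_version = as.character(utils::packageVersion("wmhcoupling")),
       seeds = seeds,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# join the wide per-network coupling onto the cohort table
coupling_wide <- function(coupling) {
  nets <- unique(coupling$network)
  ids <- unique(coupling$subject_id)
  wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nt in nets) {
    sub <- coupling[coupling$network == nt, ]
    wide[[paste0("rho_", nt)]] <- sub$rho[match(ids, sub$subject_id)]
  }
  wide
}

strata_of <- function(cohort) {
  list(all = rep(TRUE, nrow(cohort)),
       mild = cohort$severity == "mild",
       severe = cohort$severity == "severe")
}

#' Per-stratum WMH volume / coupling association battery
#'
#' One covariate-adjusted model (age + sex) per network and stratum with
#' the coupling as outcome and WMH volume as predictor; BH-FDR is applied
#' within each stratum's family of networks.
#'
#' @param tab cohort joined with wide coupling columns (`rho_<network>`).
#' @param networks network labels to model.
#' @param predictor `"wmh_volume"` (raw mL) or `"log_wmh"`.
#' @param covariates covariate set (default [covariate_sets()]
#'   `"wmh_coupling"`).
#' @return association data.frame, one row per (stratum, network).
#' @export
wmh_coupling_battery <- function(tab, networks,
                                 predictor = "wmh_volume",
                                 covariates = covariate_sets("wmh_coupling")) {
  strata <- strata_of(tab)
  out <- list()
  for (snm in names(strata)) {
    sub <- tab[strata[[snm]], , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty stratum: ", snm)
    rows <- lapply(networks, function(nt)
      linear_assoc(sub, paste0("rho_", nt), predictor,
                   covariates = covariates, stratum = snm))
    fam <- do.call(rbind, rows)
    fam$p_fdr <- fdr_bh(fam$p_raw)
    fam$outcome <- networks
    out[[snm]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-stratum coupling / cognition association battery
#'
#' One model per outcome and stratum with the cognitive score as outcome
#' and the target network's coupling as predictor, adjusted for age, sex,
#' education and WMH volume; BH-FDR per stratum over the outcome family.
#'
#' @param tab cohort joined with wide coupling columns.
#' @param outcomes cognitive score columns.
#' @param network target network label.
#' @return association data.frame, one row per (stratum, outcome).
#' @export
cognition_battery <- function(tab, outcomes, network = "FPN") {
  strata <- strata_of(tab)
  pred <- paste0("rho_", network)
  covs <- covariate_sets("coupling_cognition")
  out <- list()
  for (snm in names(strata)) {
    sub <- tab[strata[[snm]], , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty stratum: ", snm)
    rows <- lapply(outcomes, function(oc)
      linear_assoc(sub, oc, pred, covariates = covs, stratum = snm))
    fam <- do.call(rbind, rows)
    fam$p_fdr <- fdr_bh(fam$p_raw)
    out[[snm]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Table-1-style cohort summary
#'
#' Per-stratum counts, means (SD) or n (%) per variable, and the
#' between-stratum comparison p-value from [compare_groups()].
#' Percentages are always recomputed from counts, so the summary is a
#' pure function of the cohort table.
#'
#' @param cohort validated cohort data.frame with a `severity` column.
#' @param variables columns to summarize; defaults to the demographic,
#'   risk and score columns present.
#' @return object of class `cohort_summary`: list with `table` (display
#'   strings) and `stats` (long numeric data.frame: `variable`, `stratum`,
#'   `n`, `mean`, `sd`, `count`, `pct`, `p`).
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(variables)) {
    cand <- c("age", "sex", "education", "wmh_volume", "hypertension",
              "diabetes", "hypercholesterolemia", "smoking", "drinking",
              "mmse", "moca", "digit_span_forward")
    variables <- intersect(cand, names(cohort))
  }
  strata <- strata_of(cohort)
  two_strata <- all(vapply(strata[c("mild", "severe")], any, logical(1)))
  stats_rows <- list()
  disp <- data.frame(variable = c("n", variables), stringsAsFactors = FALSE)
  for (snm in names(strata)) {
    sub <- cohort[strata[[snm]], , drop = FALSE]
    ntot <- nrow(sub)
    col <- character(length(variables) + 1L)
    col[1] <- sprintf("%d (%.1f%%)", ntot, 100 * ntot / nrow(cohort))
    stats_rows[[paste0(snm, ".n")]] <- data.frame(
      variable = "n", stratum = snm, n = ntot, mean = NA_real_,
      sd = NA_real_, count = ntot, pct = 100 * ntot / nrow(cohort),
      p = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_along(variables)) {
      v <- variables[j]; x <- sub[[v]]
      if (is.character(x) || is.logical(x) ||
          (is.numeric(x) && all(x %in% c(0, 1, NA)))) {
        pos <- if (is.character(x)) x == "female" else x %in% c(1, TRUE)
        cnt <- sum(pos, na.rm = TRUE)
        pct <- if (ntot > 0) 100 * cnt / sum(!is.na(x)) else NA_real_
        col[j + 1L] <- if (ntot > 0) sprintf("%d (%.1f%%)", cnt, pct) else "0"
        stats_rows[[paste0(snm, ".", v)]] <- data.frame(
          variable = v, stratum = snm, n = sum(!is.na(x)), mean = NA_real_,
          sd = NA_real_, count = cnt, pct = pct, p = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        mu <- mean(x, na.rm = TRUE); sdv <- stats::sd(x, na.rm = TRUE)
        col[j + 1L] <- sprintf("%.2f (%.2f)", mu, sdv)
        stats_rows[[paste0(snm, ".", v)]] <- data.frame(
          variable = v, stratum = snm, n = sum(!is.na(x)), mean = mu,
          sd = sdv, count = NA_integer_, pct = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    disp[[snm]] <- col
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  disp$p <- NA_real_
  if (two_strata) {
    cmp <- compare_groups(cohort, variables, group = "severity")
    disp$p <- c(NA_real_, cmp$p)
    stats$p <- cmp$p[match(stats$variable, cmp$variable)]
  }
  structure(list(table = disp, stats = stats), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  tab <- x$table
  tab$p <- ifelse(is.na(tab$p), "",
                  ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages on a cohort table and its coupling table:
#' optional motion-QC exclusion, severity stratification (computed once
#' and joined everywhere), the Table-1-style summary, the per-stratum
#' WMH-volume / coupling battery, the coupling / cognition cross-sectional
#' battery, the longitudinal model, the across-network repeated-measures
#' ANOVA, and the quartile-outcome ROC in the mild stratum. No subject is
#' silently dropped: excluded counts are reported and reconcile with the
#' input.
#'
#' @param cohort cohort data.frame (see [read_cohort()] for the schema).
#' @param coupling long coupling table (`subject_id`, `network`, `rho`).
#' @param motion optional motion table for [motion_qc()].
#' @param outcomes cognitive outcome columns for the cross-sectional
#'   battery (defaults to those present among `digit_span_forward`,
#'   `moca`, `mmse`).
#' @param target_network network for the cognition, longitudinal and ROC
#'   analyses (default `"FPN"`).
#' @param wmh_predictor `"wmh_volume"` or `"log_wmh"`.
#' @param followup_outcome follow-up column for the longitudinal model and
#'   ROC (default `"digit_span_forward_fu"` when present).
#' @param sens_floor sensitivity floor for the ROC cutoff.
#' @return list of class `pipeline_result`: `summary`, `wmh_assoc`,
#'   `cognition_assoc`, `longitudinal`, `anova`, `roc`, `excluded`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, coupling, motion = NULL,
                         outcomes = NULL, target_network = "FPN",
                         wmh_predictor = c("wmh_volume", "log_wmh"),
                         followup_outcome = "digit_span_forward_fu",
                         sens_floor = 0.90) {
  wmh_predictor <- match.arg(wmh_predictor)
  n_in <- nrow(cohort)
  excluded <- data.frame(subject_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(motion)) {
    qc <- motion_qc(motion)
    bad <- qc$subject_id[!qc$pass]
    excluded <- rbind(excluded,
                      data.frame(subject_id = bad,
                                 reason = qc$reason[!qc$pass],
                                 stringsAsFactors = FALSE))
    cohort <- cohort[!cohort$subject_id %in% bad, , drop = FALSE]
  }
  cohort <- validate_cohort(cohort)
  stopifnot(nrow(cohort) + nrow(excluded) == n_in)
  if (!any(cohort$severity == "severe"))
    stop("empty stratum: severe (no severe-WMH subjects after exclusion)")
  if (!any(cohort$severity == "mild"))
    stop("empty stratum: mild")
  if (wmh_predictor == "log_wmh" && !"log_wmh" %in% names(cohort))
    cohort$log_wmh <- log(cohort$wmh_volume)

  nets <- unique(coupling$network)
  wide <- coupling_wide(coupling)
  tab <- merge(cohort, wide, by = "subject_id", all.x = TRUE, sort = TRUE)

  summary <- summarize_cohort(cohort)
  wmh_assoc <- wmh_coupling_battery(tab, nets, predictor = wmh_predictor)

  if (is.null(outcomes))
    outcomes <- intersect(c("digit_span_forward", "moca", "mmse"),
                          names(tab))
  cog <- if (length(outcomes))
    cognition_battery(tab, outcomes, network = target_network) else NULL

  long <- NULL
  roc <- NULL
  if (followup_outcome %in% names(tab) &&
      any(!is.na(tab[[followup_outcome]]))) {
    mild <- tab[tab$severity == "mild", , drop = FALSE]
    long <- longitudinal_assoc(mild, followup_outcome,
                               paste0("rho_", target_network),
                               stratum = "mild")
    labs <- rep(NA_character_, nrow(mild))
    obs <- !is.na(mild[[followup_outcome]])
    labs[obs] <- quartile_labels(mild[[followup_outcome]][obs])
    roc <- roc_analysis(mild[[paste0("rho_", target_network)]], labs,
                        sens_floor = sens_floor)
  }

  cmat <- as.matrix(wide[, paste0("rho_", nets), drop = FALSE])
  colnames(cmat) <- nets
  cmat <- cmat[stats::complete.cases(cmat), , drop = FALSE]
  anova <- rm_anova_networks(cmat)

  manifest <- run_manifest(list(networks = nets,
                                target_network = target_network,
                                wmh_predictor = wmh_predictor,
                                outcomes = outcomes,
                                sens_floor = sens_floor,
                                n_subjects = nrow(cohort)))
  structure(list(summary = summary, wmh_assoc = wmh_assoc,
                 cognition_assoc = cog, longitudinal = long, anova = anova,
                 roc = roc, excluded = excluded, manifest = manifest),
            class = "pipeline_result")
}

#' Write a pipeline result bundle to tidy CSVs
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @param overwrite allow clobbering.
#' @export
write_pipeline_results <- function(result, dir, overwrite = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(result$wmh_assoc, file.path(dir, "associations_wmh.csv"),
                overwrite = overwrite)
  if (!is.null(result$cognition_assoc))
    write_results(result$cognition_assoc,
                  file.path(dir, "associations_cognition.csv"),
                  overwrite = overwrite)
  if (!is.null(result$longitudinal))
    write_results(result$longitudinal,
                  file.path(dir, "associations_longitudinal.csv"),
                  overwrite = overwrite)
  write_results(result$summary$stats, file.path(dir, "summary.csv"),
                overwrite = overwrite)
  an <- result$anova
  write_results(data.frame(F = an$F, df1 = an$df1, df2 = an$df2,
                           epsilon = an$epsilon, p = an$p, n = an$n),
                file.path(dir, "anova.csv"), overwrite = overwrite)
  if (!is.null(result$roc)) {
    rr <- result$roc
    write_results(data.frame(auc = rr$auc, ci_low = rr$ci_low,
                             ci_high = rr$ci_high, cutoff = rr$cutoff,
                             sensitivity = rr$sensitivity,
                             specificity = rr$specificity,
                             n_pos = rr$n_pos, n_neg = rr$n_neg),
                  file.path(dir, "roc.csv"), overwrite = overwrite)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
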