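# Publication-shaped outputs: the main weighted report, per-stratum /
# per-site / per-age panels, fixed-horizon reports, and cutoff-scan
# tables. Reports are CSV-first; every file carries a metadata header so
# a run is exactly reproducible from (cohort, definitions, seed).

#' Round a validation report for display
#'
#' Display convention: AUC, CI, sensitivity, specificity and likelihood
#' ratios to 2 dp; PPV/NPV to 2 dp percentages. Internal computation is
#' never rounded; use this only at the reporting edge.
#'
#' @param report A validation-report data frame.
#' @return The report with display columns rounded.
#' @export
round_report <- function(report) {
  cols <- c("auc", "ci_low", "ci_high", "sensitivity", "specificity",
            "ppv", "npv", "lr_pos", "lr_neg")
  for (col in intersect(cols, names(report))) {
    report[[col]] <- round(report[[col]], 2)
  }
  report
}

#' Write a report CSV with a reproducibility header
#'
#' @param report Data frame to write.
#' @param path Output path.
#' @param seed Seed used for the run, recorded in the header.
#' @param extra Named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, seed = NA, extra = NULL) {
  meta <- c(sprintf("# seed: %s", seed),
            sprintf("# rows: %d", nrow(report)),
            if (length(extra)) sprintf("# %s: %s", names(extra), extra))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(report, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a report CSV written by [write_report_csv()]
#'
#' @param path File path.
#' @return Data frame (header comment lines skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Cutoff-scan table for a score
#'
#' Per-candidate-cutoff Youden's J, sensitivity and specificity, with the
#' optimal cutoff flagged (lowest cutoff at the maximal J). For a score
#' with range 0..R there are R + 2 candidate rows (cutoff R + 1 makes
#' nobody positive).
#'
#' @param cutoff_result A `cutoff_result` from [youden_optimal_cutoff()].
#' @param path Optional CSV output path.
#' @param seed Recorded in the file header when writing.
#' @return The per-cutoff data frame, invisibly when written.
#' @export
render_cutoff_scan <- function(cutoff_result, path = NULL, seed = NA) {
  stopifnot(inherits(cutoff_result, "cutoff_result"))
  tab <- cutoff_result$table
  if (nrow(tab) < 2) stop("cutoff scan needs at least two candidates",
                          call. = FALSE)
  if (!is.null(path)) {
    write_report_csv(tab, path, seed = seed)
    return(invisible(tab))
  }
  tab
}

#' ROC curve points for export
#'
#' Weighted TPR/FPR at every candidate cutoff, suitable for plotting.
#'
#' @inheritParams confusion_at_cutoff
#' @param range_min,range_max Score range to scan.
#' @return Data frame with `cutoff`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, outcomes, weights = rep(1, length(scores)),
                       range_min = min(scores), range_max = max(scores)) {
  scan <- youden_optimal_cutoff(scores, outcomes, weights,
                                range_min = range_min,
                                range_max = range_max)$table
  data.frame(cutoff = scan$cutoff, tpr = scan$sensitivity,
             fpr = 1 - scan$specificity)
}

#' Run the full validation and write all report files
#'
#' Orchestrates a complete run: the weighted full-cohort report, the
#' disease-restricted rows for scores with a declared target population,
#' unweighted subgroup panels (strata, sites, age bands), fixed-horizon
#' reports, and cutoff-scan tables for the scores without predefined
#' cutoffs.
#'
#' @param cohort Patient data frame.
#' @param registry Score registry; default the bundled definitions.
#' @param out_dir Output directory, created if needed.
#' @param seed Seed for all bootstrap resampling.
#' @param n_boot Bootstrap replicates per CI.
#' @param subgroups Character subset of `c("stratum", "site", "age")`.
#' @param horizons Integer vector of fixed horizons in days.
#' @return Named list of the written data frames, invisibly.
#' @export
run_validation <- function(cohort, registry = load_score_registry(),
                           out_dir = "results", seed = 1L, n_boot = 500L,
                           subgroups = c("stratum"),
                           horizons = c(2L, 5L, 7L, 30L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- score_cohort(registry, cohort)
  written <- list()

  main <- validate_all_scores(registry, cohort, scored = scored,
                              weighted = TRUE, n_boot = n_boot, seed = seed)
  main <- main[order(-main$auc), ]
  write_report_csv(round_report(main), file.path(out_dir, "main_report.csv"),
                   seed = seed)
  written$main <- main

  restricted <- do.call(rbind, lapply(registry, function(def) {
    if (is.null(def$target_population)) return(NULL)
    validate_score(def, cohort, scored = scored, weighted = TRUE,
                   restrict_to_target = TRUE,
                   subgroup_label = paste0("syndrome:", def$target_population),
                   n_boot = n_boot, seed = seed)
  }))
  if (!is.null(restricted)) {
    rownames(restricted) <- NULL
    write_report_csv(round_report(restricted),
                     file.path(out_dir, "disease_restricted_report.csv"),
                     seed = seed)
    written$disease_restricted <- restricted
  }

  for (by in subgroups) {
    rep_by <- validate_by_subgroup(registry, cohort, by = by, scored = scored,
                                   weighted = FALSE, n_boot = n_boot,
                                   seed = seed)
    write_report_csv(round_report(rep_by),
                     file.path(out_dir, sprintf("by_%s_report.csv", by)),
                     seed = seed)
    written[[paste0("by_", by)]] <- rep_by
  }

  for (h in horizons) {
    rep_h <- validate_all_scores(registry, cohort, scored = scored,
                                 weighted = TRUE, horizon = h,
                                 subgroup_label = sprintf("horizon:%d", h),
                                 n_boot = n_boot, seed = seed)
    write_report_csv(round_report(rep_h),
                     file.path(out_dir, sprintf("horizon_%02d_report.csv", h)),
                     seed = seed)
    written[[sprintf("horizon_%d", h)]] <- rep_h
  }

  for (def in registry) {
    if (!is.null(def$cutoff)) next
    sc <- .evaluate_def(def, cohort)
    keep <- sc$applicable & !is.na(sc$total_points)
    cr <- youden_optimal_cutoff(sc$total_points[keep],
                                cohort$died_inpatient[keep],
                                cohort$pop_weight[keep],
                                range_min = def$range[1],
                                range_max = def$range[2])
    render_cutoff_scan(cr, file.path(out_dir,
                                     sprintf("cutoff_scan_%s.csv", def$name)),
                       seed = seed)
    written[[paste0("cutoff_scan_", def$name)]] <- cr$table
  }
  invisible(written)
}
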