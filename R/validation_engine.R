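# Weighted validation metrics: confusion counts, sensitivity/specificity/
# PPV/NPV/likelihood ratios, weighted Mann-Whitney AUC with bootstrap CI,
# Mandrekar discrimination bands, and Youden-optimal cutoffs.

.check_so_w <- function(scores, outcomes, weights) {
  if (length(scores) != length(outcomes) ||
      length(scores) != length(weights)) {
    stop("scores, outcomes and weights must have equal length", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(outcomes)) || any(is.na(weights))) {
    stop("missing values in scores/outcomes/weights; filter before calling",
         call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  outcomes <- as.logical(outcomes)
  if (!any(outcomes) || all(outcomes)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  outcomes
}

#' Weighted confusion counts at a cutoff
#'
#' A child is predicted high-risk iff `score >= cutoff`. Counts are sums
#' of the per-child weights; with unit weights they are plain integers.
#'
#' @param scores Integer score per child.
#' @param outcomes Logical (or 0/1) death indicator.
#' @param weights Positive per-child weights.
#' @param cutoff Integer cutoff for increased mortality risk.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, outcomes,
                                weights = rep(1, length(scores)), cutoff) {
  outcomes <- .check_so_w(scores, outcomes, weights)
  pos <- scores >= cutoff
  out <- list(tp = sum(weights[pos & outcomes]),
              fp = sum(weights[pos & !outcomes]),
              tn = sum(weights[!pos & !outcomes]),
              fn = sum(weights[!pos & outcomes]))
  class(out) <- "confusion_counts"
  out
}

#' Confusion counts from four numbers
#'
#' @param tp,fp,tn,fn Nonnegative (possibly weighted) counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative",
                                       call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Secondary metrics from confusion counts
#'
#' Sensitivity and specificity as proportions, PPV/NPV as percentages,
#' and likelihood ratios computed from the unrounded proportions:
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`. PPV (NPV) is
#' `NA` with an `undefined` flag when no child is predicted positive
#' (negative).
#'
#' @param counts A `confusion_counts` object.
#' @return A `metric_set` list: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `lr_pos`, `lr_neg`, `ppv_undefined`, `npv_undefined`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn <= 0) stop("no cases (tp + fn = 0)", call. = FALSE)
  if (tn + fp <= 0) stop("no controls (tn + fp = 0)", call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv_undef <- (tp + fp) == 0
  npv_undef <- (tn + fn) == 0
  out <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = if (ppv_undef) NA_real_ else 100 * tp / (tp + fp),
    npv = if (npv_undef) NA_real_ else 100 * tn / (tn + fn),
    lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
    lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
    ppv_undefined = ppv_undef,
    npv_undefined = npv_undef
  )
  class(out) <- "metric_set"
  out
}

#' Weighted Mann-Whitney AUC
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, with children weighted by `weights`: the sum over (case i,
#' control j) pairs of `w_i * w_j * (1, 0.5, 0)` for `s_i > s_j`, tie,
#' `s_i < s_j`, divided by the total case-control weight product. With
#' unit weights this is the usual Mann-Whitney/ROC AUC. Computed by a
#' single sort over distinct score values (O(n log n)), which matches the
#' brute-force pairwise definition exactly.
#'
#' @inheritParams confusion_at_cutoff
#' @return AUC in `[0, 1]`.
#' @export
weighted_auc <- function(scores, outcomes, weights = rep(1, length(scores))) {
  outcomes <- .check_so_w(scores, outcomes, weights)
  ord <- order(scores)
  s <- scores[ord]; y <- outcomes[ord]; w <- weights[ord]
  w_case <- w * y
  w_ctrl <- w * !y
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))  # run id per distinct value
  case_g <- as.numeric(tapply(w_case, grp, sum))
  ctrl_g <- as.numeric(tapply(w_ctrl, grp, sum))
  ctrl_below <- c(0, cumsum(ctrl_g))[seq_along(ctrl_g)]
  num <- sum(case_g * (ctrl_below + 0.5 * ctrl_g))
  num / (sum(case_g) * sum(ctrl_g))
}

#' Bootstrap percentile confidence interval for the weighted AUC
#'
#' Resamples children with replacement (weights carried along) and takes
#' percentiles of the replicate AUCs. Replicates that lose one outcome
#' class are redrawn, with a retry guard.
#'
#' @inheritParams confusion_at_cutoff
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Integer seed making the interval reproducible.
#' @param conf Confidence level.
#' @param max_retry Redraw limit for degenerate replicates.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
auc_ci <- function(scores, outcomes, weights = rep(1, length(scores)),
                   n_boot = 2000L, seed = 1L, conf = 0.95,
                   max_retry = 100L) {
  outcomes <- .check_so_w(scores, outcomes, weights)
  if (n_boot < 200) stop("n_boot must be >= 200", call. = FALSE)
  n <- length(scores)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(max_retry + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(outcomes[idx]) && !all(outcomes[idx])) break
      if (try > max_retry) stop("bootstrap replicate without both classes",
                                call. = FALSE)
    }
    reps[b] <- weighted_auc(scores[idx], outcomes[idx], weights[idx])
  }
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Discrimination band for an AUC (Mandrekar convention)
#'
#' 0.8-1.0 excellent; 0.7-0.8 acceptable/good; 0.5-0.7 poor; below 0.5
#' not useful.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Character band: `excellent`, `acceptable_good`, `poor`,
#'   `not_useful`.
#' @export
classify_auc <- function(auc) {
  if (any(is.na(auc)) || any(auc < 0 | auc > 1)) {
    stop("auc must lie in [0, 1]", call. = FALSE)
  }
  ifelse(auc >= 0.8, "excellent",
         ifelse(auc >= 0.7, "acceptable_good",
                ifelse(auc >= 0.5, "poor", "not_useful")))
}

#' Youden-optimal cutoff
#'
#' Scans every candidate cutoff from `range_min` to `range_max + 1`
#' (the last makes nobody positive) and maximises Youden's
#' `J = sensitivity + specificity - 1`; the lowest cutoff attaining the
#' maximum wins (ties favour sensitivity).
#'
#' @inheritParams confusion_at_cutoff
#' @param range_min,range_max Integer score range to scan; defaults to
#'   the observed range.
#' @return A `cutoff_result` list: `cutoff`, `youden_j`, and `table`, a
#'   data frame with one row per candidate (`cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `optimal`).
#' @export
youden_optimal_cutoff <- function(scores, outcomes,
                                  weights = rep(1, length(scores)),
                                  range_min = min(scores),
                                  range_max = max(scores)) {
  outcomes <- .check_so_w(scores, outcomes, weights)
  candidates <- seq.int(range_min, range_max + 1L)
  tab <- do.call(rbind, lapply(candidates, function(k) {
    pos <- scores >= k
    sens <- sum(weights[pos & outcomes]) / sum(weights[outcomes])
    spec <- sum(weights[!pos & !outcomes]) / sum(weights[!outcomes])
    data.frame(cutoff = k, sensitivity = sens, specificity = spec,
               youden_j = sens + spec - 1)
  }))
  best <- which.max(tab$youden_j)       # which.max -> first (lowest) maximum
  tab$optimal <- seq_len(nrow(tab)) == best
  structure(list(cutoff = tab$cutoff[best], youden_j = tab$youden_j[best],
                 table = tab),
            class = "cutoff_result")
}

# ---- per-score validation --------------------------------------------------

.age_band <- function(age_months) {
  cut(age_months, breaks = c(2, 6, 12, 18, 24),
      labels = c("2-6", "6-12", "12-18", "18-24"),
      right = FALSE, include.lowest = TRUE)
}

.not_evaluable_row <- function(def, label, n, deaths) {
  data.frame(score = def$name, subgroup = label,
             range = sprintf("0-%d", def$range[2]),
             cutoff = NA_integer_, cutoff_source = NA_character_,
             auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             band = NA_character_, sensitivity = NA_real_,
             specificity = NA_real_, tp = NA_real_, fp = NA_real_,
             tn = NA_real_, fn = NA_real_, ppv = NA_real_, npv = NA_real_,
             lr_pos = NA_real_, lr_neg = NA_real_,
             deaths = deaths, n = n, evaluable = FALSE,
             stringsAsFactors = FALSE)
}

#' Validate one score against a cohort
#'
#' Applies the score's applicability predicate, any subgroup filter and
#' an optional fixed outcome horizon, then reports the weighted (or
#' unweighted) AUC with bootstrap CI and discrimination band, the cutoff
#' (predefined when the score has one, else Youden-optimal), and the
#' confusion-matrix metrics at that cutoff. A filter that removes every
#' case or every control yields a "not evaluable" row rather than an
#' error.
#'
#' @param def A `score_definition`.
#' @param cohort Patient data frame.
#' @param scored Optional precomputed [score_cohort()] output (saves
#'   rescoring).
#' @param weighted Use `pop_weight` (full-cohort analyses); subgroup
#'   analyses within strata/sites/ages conventionally use unit weights.
#' @param subset Logical vector over cohort rows, or `NULL`.
#' @param subgroup_label Label recorded in the report row.
#' @param horizon Optional fixed horizon in days for the outcome; `NULL`
#'   means in-hospital death.
#' @param restrict_to_target Restrict to the score's design syndrome
#'   (e.g. malaria for LODS), when declared.
#' @param cutoff Override the cutoff (otherwise predefined, else Youden).
#' @param n_boot,seed Bootstrap controls for the AUC CI.
#' @return One-row data frame (a validation-report row).
#' @export
validate_score <- function(def, cohort, scored = NULL, weighted = TRUE,
                           subset = NULL, subgroup_label = "all",
                           horizon = NULL, restrict_to_target = FALSE,
                           cutoff = NULL, n_boot = 500L, seed = 1L) {
  stopifnot(inherits(def, "score_definition"))
  if (is.null(scored)) {
    sc <- .evaluate_def(def, cohort)
  } else {
    sc <- scored[scored$score_name == def$name, ]
    sc <- sc[match(cohort$child_id, sc$child_id), ]
  }
  keep <- sc$applicable & !is.na(sc$total_points)
  if (!is.null(subset)) keep <- keep & subset
  if (restrict_to_target && !is.null(def$target_population)) {
    keep <- keep & cohort[[def$target_population]]
  }
  keep[is.na(keep)] <- FALSE

  outcome <- if (is.null(horizon)) cohort$died_inpatient else
    outcome_at_horizon(cohort, horizon)
  w <- if (weighted) cohort$pop_weight else rep(1, nrow(cohort))

  s <- sc$total_points[keep]; y <- outcome[keep]; ww <- w[keep]
  if (!length(s) || !any(y) || all(y)) {
    return(.not_evaluable_row(def, subgroup_label, sum(keep), sum(ww[y])))
  }

  auc <- weighted_auc(s, y, ww)
  ci <- auc_ci(s, y, ww, n_boot = n_boot, seed = seed)
  cutoff_source <- "supplied"
  if (is.null(cutoff)) {
    if (!is.null(def$cutoff)) {
      cutoff <- def$cutoff
      cutoff_source <- "predefined"
    } else {
      cutoff <- youden_optimal_cutoff(s, y, ww, range_min = def$range[1],
                                      range_max = def$range[2])$cutoff
      cutoff_source <- "youden"
    }
  }
  cc <- confusion_at_cutoff(s, y, ww, cutoff)
  m <- metrics_from_counts(cc)
  data.frame(score = def$name, subgroup = subgroup_label,
             range = sprintf("0-%d", def$range[2]),
             cutoff = as.integer(cutoff), cutoff_source = cutoff_source,
             auc = auc, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             band = classify_auc(auc),
             sensitivity = m$sensitivity, specificity = m$specificity,
             tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
             ppv = m$ppv, npv = m$npv, lr_pos = m$lr_pos, lr_neg = m$lr_neg,
             deaths = cc$tp + cc$fn, n = length(s), evaluable = TRUE,
             stringsAsFactors = FALSE)
}

#' Validate every score in a registry
#'
#' The main-report shape: one row per score, weighted, full cohort, with
#' each score's predefined cutoff or the Youden optimum.
#'
#' @inheritParams validate_score
#' @param registry Named list from [load_score_registry()].
#' @param ... Passed to [validate_score()].
#' @return Data frame, one row per registry entry.
#' @export
validate_all_scores <- function(registry, cohort, scored = NULL, ...) {
  if (is.null(scored)) scored <- score_cohort(registry, cohort)
  out <- do.call(rbind, lapply(registry, validate_score, cohort = cohort,
                               scored = scored, ...))
  rownames(out) <- NULL
  out
}

#' Subgroup validation reports
#'
#' Repeats the validation within each level of a subgroup variable:
#' nutritional stratum, site, age band (2-6, 6-12, 12-18, 18-24 months)
#' or an admission syndrome. Subgroup analyses are unweighted by
#' convention (the full-cohort analysis carries the population weights).
#'
#' @inheritParams validate_all_scores
#' @param by One of `"stratum"`, `"site"`, `"age"`, `"syndrome"`.
#' @param weighted Passed through; defaults to unweighted.
#' @return Data frame with one row per (score, subgroup level).
#' @export
validate_by_subgroup <- function(registry, cohort, by = c("stratum", "site",
                                                          "age", "syndrome"),
                                 scored = NULL, weighted = FALSE, ...) {
  by <- match.arg(by)
  if (is.null(scored)) scored <- score_cohort(registry, cohort)
  levels_of <- switch(by,
    stratum = lapply(stats::setNames(nm = c("none", "moderate", "severe")),
                     function(v) cohort$stratum == v),
    site = lapply(stats::setNames(nm = sort(unique(cohort$site))),
                  function(v) cohort$site == v),
    age = {
      band <- .age_band(cohort$age_months)
      lapply(stats::setNames(nm = levels(band)),
             function(v) !is.na(band) & band == v)
    },
    syndrome = lapply(stats::setNames(nm = c("diarrhoea", "pneumonia_lrti",
                                             "malaria", "severe_anaemia")),
                      function(v) cohort[[v]] %in% TRUE)
  )
  out <- do.call(rbind, lapply(names(levels_of), function(lv) {
    validate_all_scores(registry, cohort, scored = scored,
                        weighted = weighted, subset = levels_of[[lv]],
                        subgroup_label = paste(by, lv, sep = ":"), ...)
  }))
  rownames(out) <- NULL
  out
}
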