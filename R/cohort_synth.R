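# Synthetic stratified cohort generator.
#
# Emulates the sampling design the validation assumes: children aged 2-23
# months admitted at 9 sites, enrolled 2:1:2 across three nutritional
# strata (no / moderate / severe wasting-or-kwashiorkor), with stratum
# in-hospital mortality 3.5% / 8.1% / 20.4%, deaths concentrated in the
# first 48 h, and clinical signs drawn with probabilities increasing in a
# latent severity so every score is discriminative. Population weights
# undo the deliberate oversampling of malnourished strata.

.strata <- c("none", "moderate", "severe")

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the enrolment design the validation cohort used
#' (n = 3101, 9 sites, 2:1:2 enrolment, stratum mortality
#' 3.5%/8.1%/20.4%, syndrome prevalences 55/21/14/14%). The target
#' population proportions behind the weights are not published; the
#' default 80/10/10% is a plausible general admitted population and is
#' deliberately arbitrary.
#'
#' @param n_children Number of children to enrol.
#' @param n_sites Number of hospital sites.
#' @param enrolment_ratio Enrolment ratio over strata (none, moderate,
#'   severe).
#' @param stratum_mortality In-hospital mortality probability per stratum.
#' @param target_population_proportions Reference hospital-population
#'   stratum proportions used for the population weights; must sum to 1.
#' @param syndrome_prevalences Admission-syndrome prevalences
#'   (non-exclusive: multiple diagnoses coexist).
#' @param severity_effect Log-odds of death per unit latent severity;
#'   controls how discriminative the clinical signs are of death.
#' @param site_effect_sd SD of per-site shifts added to latent severity.
#' @param missingness_rate Probability each missable clinical measurement
#'   is absent.
#' @param oedema_prop_severe Proportion of the severe stratum with bipedal
#'   nutritional oedema (kwashiorkor).
#' @param exact_quota If `TRUE`, stratum counts follow the enrolment ratio
#'   exactly (largest-remainder apportionment); otherwise multinomial.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_children = 3101L,
                          n_sites = 9L,
                          enrolment_ratio = c(2, 1, 2),
                          stratum_mortality = c(0.035, 0.081, 0.204),
                          target_population_proportions = c(0.80, 0.10, 0.10),
                          syndrome_prevalences = c(diarrhoea = 0.55,
                                                   pneumonia_lrti = 0.21,
                                                   malaria = 0.14,
                                                   severe_anaemia = 0.14),
                          severity_effect = 1.0,
                          site_effect_sd = 0.3,
                          missingness_rate = 0.02,
                          oedema_prop_severe = 0.30,
                          exact_quota = TRUE,
                          seed = 1L) {
  cfg <- list(n_children = as.integer(n_children), n_sites = as.integer(n_sites),
              enrolment_ratio = enrolment_ratio,
              stratum_mortality = stats::setNames(stratum_mortality, .strata),
              target_population_proportions =
                stats::setNames(target_population_proportions, .strata),
              syndrome_prevalences = syndrome_prevalences,
              severity_effect = severity_effect,
              site_effect_sd = site_effect_sd,
              missingness_rate = missingness_rate,
              oedema_prop_severe = oedema_prop_severe,
              exact_quota = isTRUE(exact_quota),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_children <= 0) stop("n_children must be positive", call. = FALSE)
  if (cfg$n_sites <= 0) stop("n_sites must be positive", call. = FALSE)
  if (length(cfg$enrolment_ratio) != 3 || any(cfg$enrolment_ratio <= 0)) {
    stop("enrolment_ratio must be three positive numbers", call. = FALSE)
  }
  probs <- c(cfg$stratum_mortality, cfg$syndrome_prevalences,
             cfg$missingness_rate, cfg$oedema_prop_severe)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$missingness_rate >= 1) stop("missingness_rate must be < 1",
                                      call. = FALSE)
  tp <- cfg$target_population_proportions
  if (length(tp) != 3 || any(tp < 0) ||
      abs(sum(tp) - 1) > 1e-9) {
    stop("target_population_proportions must be three nonnegatives summing to 1",
         call. = FALSE)
  }
  if (cfg$severity_effect < 0) stop("severity_effect must be >= 0",
                                    call. = FALSE)
  invisible(cfg)
}

#' Assign a child's nutritional stratum from MUAC, age, and oedema
#'
#' Bipedal nutritional oedema (kwashiorkor) is always severe. Otherwise,
#' for age >= 6 months: MUAC >= 12.5 cm none, 11.5-12.5 moderate,
#' < 11.5 severe; for age < 6 months the thresholds are 12.0 and 11.0 cm.
#' Interval boundaries are half-open: a MUAC exactly at the upper
#' threshold belongs to the milder category, so the three strata
#' partition all valid inputs.
#'
#' @param muac_cm Mid-upper arm circumference in cm (positive).
#' @param age_months Age in months, 2-23.
#' @param oedema Logical, bipedal nutritional oedema.
#' @return Character vector over `{"none", "moderate", "severe"}`.
#' @examples
#' assign_stratum(12.5, 7, FALSE)   # "none"
#' assign_stratum(11.4, 8, FALSE)   # "severe"
#' assign_stratum(13.0, 9, TRUE)    # "severe" (kwashiorkor)
#' @export
assign_stratum <- function(muac_cm, age_months, oedema) {
  if (any(is.na(muac_cm)) || any(muac_cm <= 0)) {
    stop("muac_cm must be positive", call. = FALSE)
  }
  n <- max(length(muac_cm), length(age_months), length(oedema))
  muac_cm <- rep_len(muac_cm, n)
  age_months <- rep_len(age_months, n)
  oedema <- rep_len(oedema, n)
  hi <- ifelse(age_months >= 6, 12.5, 12.0)
  lo <- ifelse(age_months >= 6, 11.5, 11.0)
  out <- ifelse(muac_cm >= hi, "none",
                ifelse(muac_cm >= lo, "moderate", "severe"))
  out[oedema] <- "severe"
  out
}

#' Population weights undoing stratified oversampling
#'
#' Weight for a child in stratum s is `target_proportions[s] /
#' sample_proportion[s]`, so the weighted stratum shares equal the target
#' proportions exactly and the mean weight is 1.
#'
#' @param stratum Character vector of strata (or a cohort data frame with
#'   a `stratum` column).
#' @param target_proportions Named (none/moderate/severe) proportions
#'   summing to 1.
#' @return Numeric weight per child.
#' @export
compute_population_weights <- function(stratum,
                                       target_proportions = c(none = 0.80,
                                                              moderate = 0.10,
                                                              severe = 0.10)) {
  if (is.data.frame(stratum)) stratum <- stratum$stratum
  if (abs(sum(target_proportions) - 1) > 1e-9) {
    stop("target_proportions must sum to 1", call. = FALSE)
  }
  tab <- table(factor(stratum, levels = .strata))
  samp <- as.numeric(tab) / length(stratum)
  names(samp) <- .strata
  tp <- target_proportions[.strata]
  empty <- samp == 0 & tp > 0
  if (any(empty)) {
    stop("stratum absent from cohort but has nonzero target proportion: ",
         paste(.strata[empty], collapse = ", "), call. = FALSE)
  }
  w <- ifelse(samp > 0, tp / samp, 0)
  unname(w[stratum])
}

# Largest-remainder apportionment of n over ratio.
.quota_counts <- function(n, ratio) {
  share <- n * ratio / sum(ratio)
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Solve the per-stratum intercept a so that mean(plogis(a + b*z)) = target
# over the realized severity draws z; reduces to qlogis(target) when b = 0.
.calibrate_intercept <- function(target, b, z) {
  if (b == 0 || !length(z)) return(stats::qlogis(target))
  f <- function(a) mean(stats::plogis(a + b * z)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a synthetic stratified admission cohort
#'
#' Children are enrolled across the three nutritional strata per the
#' configured ratio; MUAC is drawn inside the assigned stratum's interval
#' (so [assign_stratum()] round-trips); a latent severity (standard normal
#' plus stratum and site shifts) drives both clinical signs and death;
#' per-stratum death-model intercepts are calibrated so the expected
#' mortality equals the configured stratum rates; deaths are front-loaded
#' (most within 48 h of admission) via a geometric day-of-death
#' distribution; population weights are attached.
#'
#' @param config A [cohort_config()].
#' @return Data frame, one row per child, columns [patient_fields()];
#'   the generating config and the latent severity vector are attached as
#'   attributes `config` and `latent_severity`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_children
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(withr_seed)

  # strata and enrolment
  if (config$exact_quota) {
    counts <- .quota_counts(n, config$enrolment_ratio)
    stratum <- sample(rep(.strata, counts))
  } else {
    stratum <- sample(.strata, n, replace = TRUE,
                      prob = config$enrolment_ratio / sum(config$enrolment_ratio))
  }
  site <- paste0("site", sample.int(config$n_sites, n, replace = TRUE))
  site_shift <- stats::setNames(
    stats::rnorm(config$n_sites, 0, config$site_effect_sd),
    paste0("site", seq_len(config$n_sites)))

  age <- sample(2:23, n, replace = TRUE)

  # oedema (severe stratum only) and MUAC inside the stratum interval
  oedema <- stratum == "severe" & stats::runif(n) < config$oedema_prop_severe
  lo_thr <- ifelse(age >= 6, 11.5, 11.0)
  hi_thr <- ifelse(age >= 6, 12.5, 12.0)
  muac <- numeric(n)
  i <- stratum == "none"
  muac[i] <- stats::runif(sum(i), hi_thr[i], hi_thr[i] + 3)
  i <- stratum == "moderate"
  muac[i] <- stats::runif(sum(i), lo_thr[i], hi_thr[i])
  i <- stratum == "severe" & !oedema
  muac[i] <- stats::runif(sum(i), lo_thr[i] - 2.5, lo_thr[i])
  i <- stratum == "severe" & oedema   # kwashiorkor: MUAC may be anything
  muac[i] <- stats::runif(sum(i), lo_thr[i] - 2.5, lo_thr[i] + 2.5)

  waz_centre <- c(none = -0.5, moderate = -2.2, severe = -3.3)
  waz <- stats::rnorm(n, waz_centre[stratum], 0.8)

  # latent severity: sicker in more malnourished strata and at some sites
  sev_shift <- c(none = 0, moderate = 0.2, severe = 0.4)
  z <- stats::rnorm(n) + sev_shift[stratum] + site_shift[site]
  z <- as.numeric(z - mean(z))

  # death: per-stratum intercept calibrated on the realized severities
  b <- config$severity_effect
  p_death <- numeric(n)
  for (s in .strata) {
    i <- stratum == s
    a <- .calibrate_intercept(config$stratum_mortality[[s]], b, z[i])
    p_death[i] <- stats::plogis(a + b * z[i])
  }
  died <- stats::runif(n) < p_death

  # clinical signs: Bernoulli, logit-linear in severity
  sign_par <- list(                       # c(baseline prevalence, slope)
    convulsions     = c(0.06, 0.8),
    deep_breathing  = c(0.12, 1.0),
    chest_indrawing = c(0.20, 0.8),
    wheeze          = c(0.10, 0.2),
    stridor         = c(0.02, 0.6),
    prostration     = c(0.10, 1.1),
    unable_to_drink = c(0.12, 1.0),
    vomits_everything = c(0.10, 0.5),
    refusal_to_feed = c(0.15, 0.9)
  )
  signs <- lapply(sign_par, function(p) {
    stats::runif(n) < stats::plogis(stats::qlogis(p[1]) + p[2] * z)
  })

  # ordinal fields via a latent with logistic noise (proportional odds)
  cons_lat <- z + stats::rlogis(n)
  consciousness <- ifelse(cons_lat > 3.4, "unresponsive",
                   ifelse(cons_lat > 2.6, "pain",
                   ifelse(cons_lat > 1.8, "verbal", "alert")))
  cap_lat <- z + stats::rlogis(n)
  cap_refill <- ifelse(cap_lat > 3.2, "gt3s",
                ifelse(cap_lat > 1.8, "s2to3", "lt2s"))

  spo2 <- .rtruncnorm(n, 96 - 3 * pmax(z, 0), 3, 50, 100)
  heart_rate <- .rtruncnorm(n, 135 + 12 * z, 15, 60, 260)
  resp_rate <- .rtruncnorm(n, 42 + 7 * z, 8, 15, 120)
  temperature <- .rtruncnorm(n, 37.6 + 0.25 * z, 0.9, 34, 42)

  hiv <- sample(c("negative", "positive", "unknown"), n, replace = TRUE,
                prob = c(0.90, 0.07, 0.03))
  syn <- lapply(config$syndrome_prevalences, function(p) stats::runif(n) < p)

  # event times: deaths front-loaded (~78% by day 2) and earlier for the
  # sickest (severity raises the daily hazard), discharges later
  day_of_death <- rep(NA_integer_, n)
  p_day <- stats::plogis(stats::qlogis(0.40) + 0.5 * z[died])
  day_of_death[died] <- pmin(stats::rgeom(sum(died), p_day), 30L)
  day_of_discharge <- rep(NA_integer_, n)
  day_of_discharge[!died] <- 1L + pmin(stats::rgeom(sum(!died), 0.25), 59L)

  cohort <- data.frame(
    child_id = sprintf("C%05d", seq_len(n)),
    site = site,
    age_months = age,
    muac_cm = muac,
    oedema = oedema,
    waz = waz,
    temperature_c = temperature,
    heart_rate = heart_rate,
    resp_rate = resp_rate,
    spo2_pct = spo2,
    cap_refill = cap_refill,
    consciousness = consciousness,
    convulsions = signs$convulsions,
    deep_breathing = signs$deep_breathing,
    chest_indrawing = signs$chest_indrawing,
    wheeze = signs$wheeze,
    stridor = signs$stridor,
    prostration = signs$prostration,
    unable_to_drink = signs$unable_to_drink,
    vomits_everything = signs$vomits_everything,
    refusal_to_feed = signs$refusal_to_feed,
    hiv_status = hiv,
    diarrhoea = syn$diarrhoea,
    pneumonia_lrti = syn$pneumonia_lrti,
    malaria = syn$malaria,
    severe_anaemia = syn$severe_anaemia,
    stratum = stratum,
    died_inpatient = died,
    day_of_death = day_of_death,
    day_of_discharge = day_of_discharge,
    stringsAsFactors = FALSE
  )
  cohort$pop_weight <- compute_population_weights(
    cohort$stratum, config$target_population_proportions)

  if (config$missingness_rate > 0) {
    missable <- c("temperature_c", "heart_rate", "resp_rate", "spo2_pct",
                  "cap_refill", "waz", "wheeze", "stridor")
    for (f in missable) {
      cohort[[f]][stats::runif(n) < config$missingness_rate] <- NA
    }
  }
  attr(cohort, "config") <- config
  attr(cohort, "latent_severity") <- z
  cohort
}

#' Death by a fixed horizon
#'
#' @param record A patient data frame (one or more rows).
#' @param horizon_days Positive integer horizon (the standard analysis
#'   points are 2, 5, 7 and 30 days).
#' @param include_post_discharge Count deaths recorded after discharge
#'   (when a death day is known) as events; if `FALSE` only inpatient
#'   deaths count.
#' @return Logical: died on or before the horizon.
#' @export
outcome_at_horizon <- function(record, horizon_days,
                               include_post_discharge = TRUE) {
  if (length(horizon_days) != 1 || horizon_days <= 0) {
    stop("horizon_days must be a positive integer", call. = FALSE)
  }
  dd <- record$day_of_death
  dis <- record$day_of_discharge
  if (any(is.na(dd) & is.na(dis))) {
    stop("record with neither day_of_death nor day_of_discharge",
         call. = FALSE)
  }
  ev <- !is.na(dd) & dd <= horizon_days
  if (!include_post_discharge) ev <- ev & record$died_inpatient
  ev
}

#' Write / read a cohort as CSV
#'
#' CSV dialect shared with the score calculators: one row per child,
#' columns named exactly as [patient_fields()], missing values as empty
#' cells.
#'
#' @param cohort Cohort data frame.
#' @param path Output file.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  logi <- c("oedema", "convulsions", "deep_breathing", "chest_indrawing",
            "wheeze", "stridor", "prostration", "unable_to_drink",
            "vomits_everything", "refusal_to_feed", "diarrhoea",
            "pneumonia_lrti", "malaria", "severe_anaemia", "died_inpatient")
  for (f in intersect(logi, names(df))) df[[f]] <- as.logical(df[[f]])
  df
}
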