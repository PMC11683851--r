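# Fixture builders and independent oracles shared across test files.

# One patient record with every sign normal/absent; override fields via ...
make_patient <- function(...) {
  p <- data.frame(
    child_id = "C1", site = "site1", age_months = 10, muac_cm = 13.5,
    oedema = FALSE, waz = -0.5, temperature_c = 37.0, heart_rate = 120,
    resp_rate = 30, spo2_pct = 98, cap_refill = "lt2s",
    consciousness = "alert", convulsions = FALSE, deep_breathing = FALSE,
    chest_indrawing = FALSE, wheeze = FALSE, stridor = FALSE,
    prostration = FALSE, unable_to_drink = FALSE, vomits_everything = FALSE,
    refusal_to_feed = FALSE, hiv_status = "negative", diarrhoea = FALSE,
    pneumonia_lrti = FALSE, malaria = FALSE, severe_anaemia = FALSE,
    stratum = "none", pop_weight = 1, died_inpatient = FALSE,
    day_of_death = NA_integer_, day_of_discharge = 3L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# A patient with every clinical sign maximally abnormal.
make_worst_patient <- function(...) {
  make_patient(
    muac_cm = 10, oedema = TRUE, waz = -4, temperature_c = 35,
    heart_rate = 200, resp_rate = 70, spo2_pct = 80, cap_refill = "gt3s",
    consciousness = "unresponsive", convulsions = TRUE,
    deep_breathing = TRUE, chest_indrawing = TRUE, wheeze = TRUE,
    stridor = TRUE, prostration = TRUE, unable_to_drink = TRUE,
    vomits_everything = TRUE, refusal_to_feed = TRUE, stratum = "severe",
    died_inpatient = TRUE, day_of_death = 1L, day_of_discharge = NA_integer_,
    ...
  )
}

# Random valid patients for property tests (n rows).
make_random_patients <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    child_id = sprintf("R%05d", seq_len(n)),
    site = paste0("site", sample.int(9, n, TRUE)),
    age_months = sample(2:23, n, TRUE),
    muac_cm = round(runif(n, 8.5, 16), 1),
    oedema = runif(n) < 0.1,
    waz = round(rnorm(n, -2, 1.5), 2),
    temperature_c = round(runif(n, 34.5, 41.5), 1),
    heart_rate = round(runif(n, 70, 220)),
    resp_rate = round(runif(n, 15, 90)),
    spo2_pct = round(runif(n, 60, 100)),
    cap_refill = sample(c("lt2s", "s2to3", "gt3s"), n, TRUE),
    consciousness = sample(c("alert", "verbal", "pain", "unresponsive"),
                           n, TRUE),
    convulsions = runif(n) < 0.2, deep_breathing = runif(n) < 0.2,
    chest_indrawing = runif(n) < 0.3, wheeze = runif(n) < 0.2,
    stridor = runif(n) < 0.1, prostration = runif(n) < 0.2,
    unable_to_drink = runif(n) < 0.2, vomits_everything = runif(n) < 0.2,
    refusal_to_feed = runif(n) < 0.2,
    hiv_status = sample(c("negative", "positive", "unknown"), n, TRUE),
    diarrhoea = runif(n) < 0.5, pneumonia_lrti = runif(n) < 0.2,
    malaria = runif(n) < 0.15, severe_anaemia = runif(n) < 0.15,
    stratum = "none", pop_weight = 1,
    died_inpatient = runif(n) < 0.1,
    day_of_death = NA_integer_, day_of_discharge = 2L,
    stringsAsFactors = FALSE
  )
}

# Independent brute-force oracle: weighted pairwise concordance.
brute_force_auc <- function(scores, outcomes, weights) {
  ci <- which(as.logical(outcomes))
  cj <- which(!as.logical(outcomes))
  gt <- outer(scores[ci], scores[cj], ">")
  eq <- outer(scores[ci], scores[cj], "==")
  ww <- outer(weights[ci], weights[cj])
  sum(ww * (gt + 0.5 * eq)) / sum(ww)
}

# Independent exhaustive-scan oracle for the Youden-optimal cutoff.
exhaustive_youden <- function(scores, outcomes, weights, lo, hi) {
  outcomes <- as.logical(outcomes)
  best_k <- NA
  best_j <- -Inf
  for (k in lo:(hi + 1)) {
    pos <- scores >= k
    sens <- sum(weights[pos & outcomes]) / sum(weights[outcomes])
    spec <- sum(weights[!pos & !outcomes]) / sum(weights[!outcomes])
    j <- sens + spec - 1
    if (j > best_j + 1e-15) {
      best_j <- j
      best_k <- k
    }
  }
  list(cutoff = best_k, youden_j = best_j)
}
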