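test_that("confusion counts are weight sums with score >= cutoff positive", {
  cc <- confusion_at_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), rep(1, 4), 2)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2, fp = 0, tn = 2, fn = 0))
  cc <- confusion_at_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), c(2, 1, 1, 1), 2)
  expect_equal(cc$tn, 3)
  cc <- confusion_at_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), rep(1, 4), 0)
  expect_equal(cc$tn, 0)
  expect_equal(cc$fn, 0)
  expect_error(confusion_at_cutoff(1:3, c(0, 1), rep(1, 2), 1), "equal length")
  expect_error(confusion_at_cutoff(1:2, c(0, 1), c(1, -1), 1), "positive")
  expect_error(confusion_at_cutoff(1:2, c(0, 0), c(1, 1), 1), "case")
})

test_that("metric formulas reproduce hand-computed and reference values", {
  m <- metrics_from_counts(confusion_counts(218, 2909, 2852, 16))
  expect_equal(round(m$sensitivity, 2), 0.93)
  expect_equal(round(m$specificity, 2), 0.50)
  expect_equal(round(m$ppv, 2), 6.97)
  expect_equal(round(m$npv, 2), 99.44)
  expect_equal(round(m$lr_pos, 2), 1.84)
  expect_equal(round(m$lr_neg, 2), 0.14)

  m <- metrics_from_counts(confusion_counts(60, 157, 5604, 174))
  expect_equal(round(m$ppv, 2), 27.65)
  expect_equal(round(m$lr_pos, 2), 9.41)

  m <- metrics_from_counts(confusion_counts(0, 0, 10, 5))
  expect_equal(m$sensitivity, 0)
  expect_true(m$ppv_undefined)
  expect_true(is.na(m$ppv))

  expect_error(metrics_from_counts(confusion_counts(0, 1, 2, 0)), "cases")
  expect_error(metrics_from_counts(confusion_counts(1, 0, 0, 1)), "controls")
})

test_that("weighted AUC handles perfect ranking, ties, and a hand-worked tie case", {
  expect_equal(weighted_auc(1:4, c(0, 0, 1, 1)), 1.0)
  expect_equal(weighted_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  # 4 case-control pairs, one tied at 0.5: (2+2+0.5+1)/4 ... brute = 0.875
  expect_equal(weighted_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_error(weighted_auc(1:3, c(1, 1, 1)), "case")
})

test_that("rank-based weighted AUC equals the brute-force pairwise oracle", {
  set.seed(2024)
  for (rep_i in 1:500) {
    n <- sample(4:50, 1)
    scores <- sample(0:8, n, replace = TRUE)
    outcomes <- c(0, 1, rbinom(n - 2, 1, 0.3))  # guarantee both classes
    weights <- runif(n, 0.2, 3)
    expect_equal(weighted_auc(scores, outcomes, weights),
                 brute_force_auc(scores, outcomes, weights),
                 tolerance = 1e-12)
  }
})

test_that("unweighted AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- sample(0:10, 400, replace = TRUE)
  outcomes <- rbinom(400, 1, plogis(-2 + 0.3 * scores))
  ours <- weighted_auc(scores, outcomes, rep(1, 400))
  theirs <- as.numeric(pROC::auc(pROC::roc(outcomes, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("AUC and metrics are invariant to rescaling all weights", {
  set.seed(5)
  n <- 200
  scores <- sample(0:6, n, TRUE)
  outcomes <- c(0, 1, rbinom(n - 2, 1, 0.2))
  w <- runif(n, 0.5, 2)
  for (c_mult in c(0.01, 7, 1000)) {
    expect_equal(weighted_auc(scores, outcomes, w),
                 weighted_auc(scores, outcomes, c_mult * w))
    m1 <- metrics_from_counts(confusion_at_cutoff(scores, outcomes, w, 3))
    m2 <- metrics_from_counts(confusion_at_cutoff(scores, outcomes,
                                                  c_mult * w, 3))
    for (f in c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
                "lr_neg")) {
      expect_equal(m1[[f]], m2[[f]])
    }
  }
})

test_that("complement symmetry: AUC(s) + AUC(-s) = 1 on tie-free data", {
  set.seed(9)
  scores <- sample(1:1000, 300)         # tie-free
  outcomes <- c(0, 1, rbinom(298, 1, 0.3))
  w <- runif(300, 0.5, 2)
  expect_equal(weighted_auc(scores, outcomes, w) +
                 weighted_auc(-scores, outcomes, w), 1)
})

test_that("AUC converges to the binormal closed form on large samples", {
  set.seed(123)
  n <- 100000
  outcomes <- rbinom(n, 1, 0.1)
  scores <- rnorm(n, mean = outcomes)   # cases N(1,1), controls N(0,1)
  closed_form <- pnorm(1 / sqrt(2))
  expect_equal(weighted_auc(scores, outcomes, rep(1, n)), closed_form,
               tolerance = 0.01)
})

test_that("discrimination bands follow the Mandrekar convention with closed lower edges", {
  expect_equal(classify_auc(c(0.80, 0.95, 1.0)),
               rep("excellent", 3))
  expect_equal(classify_auc(c(0.70, 0.79)), rep("acceptable_good", 2))
  expect_equal(classify_auc(c(0.50, 0.69)), rep("poor", 2))
  expect_equal(classify_auc(c(0, 0.49)), rep("not_useful", 2))
  expect_error(classify_auc(1.2), "0, 1")
  expect_error(classify_auc(-0.1), "0, 1")
})

test_that("Youden cutoff maximises J, matching the exhaustive oracle, ties to the lowest", {
  cr <- youden_optimal_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1))
  expect_equal(cr$cutoff, 2)
  expect_equal(cr$youden_j, 1)

  cr <- youden_optimal_cutoff(0:5, c(0, 0, 0, 1, 0, 1))
  expect_equal(cr$cutoff, 3)
  expect_equal(cr$youden_j, 0.75)
  expect_equal(nrow(cr$table), 7)       # cutoffs 0..6
  expect_true(cr$table$optimal[cr$table$cutoff == 3])

  # constant score: J = 0 everywhere, lowest candidate wins
  cr <- youden_optimal_cutoff(rep(2, 8), c(0, 1, 0, 1, 0, 1, 0, 1),
                              range_min = 0, range_max = 5)
  expect_true(all(abs(cr$table$youden_j) < 1e-12))
  expect_equal(cr$cutoff, 0)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:60, 1)
    scores <- sample(0:9, n, TRUE)
    outcomes <- c(0, 1, rbinom(n - 2, 1, 0.4))
    w <- runif(n, 0.2, 2)
    got <- youden_optimal_cutoff(scores, outcomes, w, range_min = 0,
                                 range_max = 9)
    want <- exhaustive_youden(scores, outcomes, w, 0, 9)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$youden_j)
  }
})

test_that("bootstrap CI is seed-deterministic and attains 1 under perfect separation", {
  scores <- c(rep(0, 30), rep(5, 10))
  outcomes <- c(rep(0, 30), rep(1, 10))
  ci <- auc_ci(scores, outcomes, n_boot = 300, seed = 4)
  expect_equal(unname(ci["ci_high"]), 1.0)
  expect_identical(ci, auc_ci(scores, outcomes, n_boot = 300, seed = 4))
  expect_error(auc_ci(scores, outcomes, n_boot = 50, seed = 1), ">= 200")

  # on overlapping data the interval depends on the seed (and only the seed)
  set.seed(1)
  s <- sample(0:5, 200, TRUE)
  y <- rbinom(200, 1, plogis(-1 + 0.3 * s))
  y[1:2] <- c(0, 1)
  ci_a <- auc_ci(s, y, n_boot = 300, seed = 4)
  expect_identical(ci_a, auc_ci(s, y, n_boot = 300, seed = 4))
  expect_false(identical(ci_a, auc_ci(s, y, n_boot = 300, seed = 5)))
})

test_that("bootstrap CI covers the generator's large-sample AUC at the nominal rate", {
  big <- generate_cohort(cohort_config(n_children = 100000,
                                       missingness_rate = 0, seed = 900))
  reg <- load_score_registry()
  sc_big <- score_cohort(reg["PEDIA_late"], big)
  target <- weighted_auc(sc_big$total_points, big$died_inpatient,
                         big$pop_weight)
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(n_children = 2000,
                                        missingness_rate = 0,
                                        seed = 1000 + r))
    sc <- score_cohort(reg["PEDIA_late"], co)
    ci <- auc_ci(sc$total_points, co$died_inpatient, co$pop_weight,
                 n_boot = 200, seed = r)
    if (target >= ci["ci_low"] && target <= ci["ci_high"]) hits <- hits + 1
  }
  expect_gte(hits, 0.90 * n_rep)
})

test_that("validate_score applies filters, picks cutoffs, and degrades gracefully", {
  reg <- load_score_registry()
  co <- generate_cohort(cohort_config(n_children = 2500, seed = 17))

  row <- validate_score(reg$PEDIA_early, co, n_boot = 250, seed = 2)
  expect_equal(row$cutoff_source, "youden")
  expect_equal(row$band, classify_auc(row$auc))
  expect_true(row$ci_low <= row$auc && row$auc <= row$ci_high)
  expect_equal(row$deaths, row$tp + row$fn)

  row <- validate_score(reg$LODS, co, n_boot = 250, seed = 2)
  expect_equal(row$cutoff, 1L)
  expect_equal(row$cutoff_source, "predefined")

  # malaria-restricted analysis uses only flagged children
  row_m <- validate_score(reg$LODS, co, restrict_to_target = TRUE,
                          n_boot = 250, seed = 2)
  expect_lte(row_m$n, sum(co$malaria))

  # a perfect synthetic marker: AUC 1, band excellent
  toy <- co[1:200, ]
  toy$died_inpatient <- c(rep(TRUE, 20), rep(FALSE, 180))
  fake_def <- reg$LODS
  fake_scores <- data.frame(child_id = toy$child_id, score_name = "LODS",
                            total_points = ifelse(toy$died_inpatient, 3L, 0L),
                            n_items_missing = 0L, applicable = TRUE)
  row_p <- validate_score(fake_def, toy, scored = fake_scores,
                          weighted = FALSE, n_boot = 250, seed = 2)
  expect_equal(row_p$auc, 1.0)
  expect_equal(row_p$band, "excellent")

  # filter that removes every case -> explicit not-evaluable row
  alive <- co$died_inpatient == FALSE
  row_ne <- validate_score(reg$LODS, co, subset = alive, n_boot = 250,
                           seed = 2)
  expect_false(row_ne$evaluable)
  expect_true(is.na(row_ne$auc))
})

test_that("early-horizon mortality is at least as predictable as late-horizon", {
  reg <- load_score_registry()
  co <- generate_cohort(cohort_config(seed = 1))
  sc <- score_cohort(reg, co)
  for (nm in c("PEDIA_early", "RISC_Malawi")) {
    r2 <- validate_score(reg[[nm]], co, scored = sc, horizon = 2,
                         n_boot = 250, seed = 2)
    r30 <- validate_score(reg[[nm]], co, scored = sc, horizon = 30,
                          n_boot = 250, seed = 2)
    expect_gte(r2$auc, r30$auc)
  }
})

test_that("deaths and survivor totals are conserved across scores and cutoffs", {
  reg <- load_score_registry()
  co <- generate_cohort(cohort_config(n_children = 2000, seed = 23))
  co$hiv_status <- "negative"           # make every score applicable
  sc <- score_cohort(reg, co)
  sc$total_points[is.na(sc$total_points)] <- 0L
  totals <- lapply(names(reg), function(nm) {
    s <- sc$total_points[sc$score_name == nm]
    k <- sample(0:reg[[nm]]$range[2], 1)
    cc <- confusion_at_cutoff(s, co$died_inpatient, co$pop_weight, k)
    c(cases = cc$tp + cc$fn, controls = cc$tn + cc$fp)
  })
  totals <- do.call(rbind, totals)
  expect_equal(max(totals[, "cases"]) - min(totals[, "cases"]), 0)
  expect_equal(max(totals[, "controls"]) - min(totals[, "controls"]), 0)
})
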