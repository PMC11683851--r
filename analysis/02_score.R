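#!/usr/bin/env Rscript
# Apply all eleven score calculators to the simulated cohort and summarise
# the score distributions by outcome. Writes results/scores_long.csv.

library(pewsval)

cohort <- read_cohort_csv("results/cohort.csv")
registry <- load_score_registry()
scored <- score_cohort(registry, cohort)
write.csv(scored, "results/scores_long.csv", row.names = FALSE)

died <- cohort$died_inpatient[match(scored$child_id, cohort$child_id)]
summ <- do.call(rbind, lapply(split(seq_len(nrow(scored)),
                                    scored$score_name), function(i) {
  data.frame(score = scored$score_name[i[1]],
             mean_survivors = mean(scored$total_points[i][!died[i]],
                                   na.rm = TRUE),
             mean_deaths = mean(scored$total_points[i][died[i]],
                                na.rm = TRUE),
             pct_applicable = 100 * mean(scored$applicable[i]))
}))
write.csv(summ, "results/score_summary.csv", row.names = FALSE)
cat("Mean score in deaths vs survivors (higher in deaths = discriminative):\n")
print(summ[order(-(summ$mean_deaths - summ$mean_survivors)), ],
      row.names = FALSE, digits = 3)
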