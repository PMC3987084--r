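#!/usr/bin/env Rscript
# The in-table reproduction: recover the published G7PS formula from the
# packaged cohort by least squares, score every patient, and report the
# learning/test confusion matrices, the learning-set G7S medians and the
# Youden-optimal G7S cutoff. All numbers here are recomputed from the
# packaged table, none are transcribed.

suppressPackageStartupMessages(library(g7ps))
dir.create("results", showWarnings = FALSE)

cohort <- load_cohort_table()
model <- recover_published_model(cohort)
print(model)
cat("max |residual| against printed scores:",
    signif(max(abs(attr(model, "residuals"))), 3), "\n\n")

cohort$score <- g7ps_score(model, cohort$g7s_percent, cohort$g7nl_grade)
cohort$predicted <- classify_g7ps(cohort$score)

for (co in c("learning", "test")) {
  sub <- cohort[cohort$cohort == co, ]
  perf <- evaluate_predictions(sub$predicted, sub$group)
  cat(co, "cases (n =", nrow(sub), "):\n")
  print(perf)
  cat("\n")
}

learning <- cohort[cohort$cohort == "learning", ]
g7s_frac <- learning$g7s_percent / 100
cat("learning median G7S: group R",
    median(g7s_frac[learning$group == "R"]), ", group S",
    median(g7s_frac[learning$group == "S"]), "\n")
cut <- optimal_cutoff(g7s_frac, learning$group)
cat(sprintf("Youden-optimal G7S cutoff %.3f (sens %.1f%%, spec %.1f%%)\n",
            cut$cutoff, 100 * cut$sensitivity, 100 * cut$specificity))

# also fit the discriminant afresh on the learning cases, as in the study
lda_model <- fit_discriminant(learning)
cat("\nrefit Fisher discriminant on the 18 learning cases:\n")
print(lda_model)

write_g7ps_model(model, "results/g7ps_model.json")
scatter <- cohort[, c("patient_no", "cohort", "group", "score", "predicted")]
write.table(scatter, "results/g7ps_scores.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("written: results/g7ps_model.json, results/g7ps_scores.tsv\n")
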