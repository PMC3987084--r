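#!/usr/bin/env Rscript
# Synthetic re-enactment of the LC-MS screen: generate a 9 + 9 cohort with
# planted resistance markers, align and normalize the runs, apply the
# Mann-Whitney/AUC + annotation + abundance + ratio funnel, and run stepwise
# discriminant selection on the survivors. The raw study data are not
# deposited, so the screen is demonstrated on generated data whose truth is
# known, and recovery of the planted markers is reported.

suppressPackageStartupMessages(library(g7ps))
dir.create("results", showWarnings = FALSE)
seed <- 20140207 %% 10000

sim <- generate_peak_dataset(n_per_group = 9, n_peaks = 200,
                             n_informative = 4, ratio_rs = 0.4, cv = 0.5,
                             duplicate_runs = 2, seed = seed)
pm <- align_peaks(sim$observations, mz_tol = 0.5, rt_tol = 0.4,
                  sample_groups = sim$truth$sample_groups)
cat("aligned", nrow(pm$peak_meta), "peaks from",
    nrow(sim$observations), "observations (true peaks: 200)\n")
pm <- normalize_intensities(pm)
st <- compute_peak_statistics(pm)

# annotate: planted markers get credible identifications, the rest a mix
inf_aligned <- truth_map <- tapply(pm$assignment, sim$truth$obs_peak,
                                   function(x) x[1])
inf_aligned <- truth_map[which(sim$truth$peaks$informative)]
set.seed(seed + 1)
ann_ids <- unique(c(inf_aligned, sample(st$peak_id, 60)))
annotations <- data.frame(
  peak_id = ann_ids,
  mascot_score = ifelse(ann_ids %in% inf_aligned, runif(length(ann_ids), 60, 120),
                        runif(length(ann_ids), 20, 110)),
  protein = ifelse(ann_ids %in% inf_aligned, "Galectin-7",
                   sample(c("Keratin, type II cytoskeletal 1", "Annexin A1",
                            "Desmoplakin", "Histone H4", "Plakophilin-1"),
                          length(ann_ids), replace = TRUE)))

rep <- funnel_filter(st, annotations)
print(rep)
surv <- funnel_survivors(rep)
cat("planted markers among final survivors:",
    sum(inf_aligned %in% surv), "of", length(inf_aligned), "\n")

# stepwise discriminant on log intensities of the funnel survivors
pm_log <- pm
pm_log$intensities <- log1p(pm_log$intensities)
sel <- stepwise_discriminant_select(pm_log, candidate_ids = surv)
cat("stepwise-selected peak ids:", paste(sel, collapse = ", "),
    "(Wilks' lambda", signif(attr(sel, "wilks_lambda"), 3), ")\n")
cat("selected peaks that are planted markers:",
    sum(sel %in% inf_aligned), "of", length(sel), "\n")

write_funnel_report(rep, "results/ms_funnel_report.json")
write.csv(st[st$peak_id %in% surv, ], "results/ms_funnel_survivors.csv",
          row.names = FALSE)
write_truth(sim$truth, "results/ms_truth.json")
cat("written: results/ms_funnel_report.json, results/ms_funnel_survivors.csv\n")
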