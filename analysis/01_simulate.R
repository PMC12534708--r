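#!/usr/bin/env Rscript
# Generate the synthetic study cohort: matched 5modC/5hmC beta matrices for
# 40 samples over 5 tissue archetypes (5,000 probes, logit noise 0.5), with
# planted tissue markers, age/sex effects, imprinted loci, a bounded 5hmC
# layer, replicate probes and 1% missingness. All later drivers read these
# files, so the whole analysis is reproducible from this seed alone.

library(ternarycode)

seed <- 20
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_cohort(sim_config(seed = seed))
write_beta_matrix(sim$modc, "results/data/modc.tsv")
write_beta_matrix(sim$hmc, "results/data/hmc.tsv")
data.table::fwrite(sim$sheet, "results/data/sample_sheet.csv")
data.table::fwrite(sim$manifest, "results/data/manifest.tsv", sep = "\t")
# ground truth sidecars, plain text only
write_probe_set(sim$truth$markers$probe_id, "results/data/true_marker_probes.txt")
data.table::fwrite(sim$truth$markers, "results/data/true_markers.tsv", sep = "\t")
data.table::fwrite(sim$truth$age_cpgs, "results/data/true_age_cpgs.tsv", sep = "\t")
write_probe_set(sim$truth$sex_cpgs$male_hyper, "results/data/sex_male_hyper.txt")
write_probe_set(sim$truth$sex_cpgs$male_hypo, "results/data/sex_male_hypo.txt")
data.table::fwrite(
  data.frame(tissue = names(sim$truth$prolif_by_tissue),
             proliferation = sim$truth$prolif_by_tissue),
  "results/data/true_proliferation.csv")

cat(sprintf("cohort: %d probes x %d samples, %d tissues\n",
            nrow(sim$modc), ncol(sim$modc),
            length(unique(sim$sheet$tissue))))
cat(sprintf("planted: %d markers, %d age-CpGs, %d sex-CpGs, %d imprinted\n",
            nrow(sim$truth$markers), nrow(sim$truth$age_cpgs),
            length(unlist(sim$truth$sex_cpgs)),
            length(sim$truth$imprinted)))
cat(sprintf("missingness: %.2f%% of 5modC cells\n", 100 * mean(is.na(sim$modc))))
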