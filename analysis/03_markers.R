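#!/usr/bin/env Rscript
# One-vs-rest tissue marker discovery (Wilcoxon/AUC/delta-beta with the
# 10%/50% NA rules), scored against the planted ground truth, plus the
# constitutive / intermediate methylation screens and the variability
# ranking used by set enrichment.

library(ternarycode)

manifest <- read_manifest("results/data/manifest.tsv")
modc <- collapse_replicates(read_beta_matrix("results/data/modc.tsv"), manifest)
sheet <- read_sample_sheet("results/data/sample_sheet.csv")
truth <- data.table::fread("results/data/true_markers.tsv")
dir.create("results/markers", showWarnings = FALSE, recursive = TRUE)

groups <- setNames(sheet$tissue, sheet$sample_id)
res <- all_contrasts(modc, groups, min_auc = 0.8, min_delta = 0.2)
tab <- do.call(rbind, res)
data.table::fwrite(tab, "results/markers/markers.tsv", sep = "\t")

sel <- tab[tab$selected, ]
hit <- paste(sel$probe_id, sel$contrast) %in% paste(truth$probe_id, truth$celltype)
cat(sprintf("markers: %d selected (AUC >= 0.8, |delta beta| >= 0.2); precision %.3f, recall %.3f vs %d planted\n",
            nrow(sel), sum(hit) / nrow(sel), sum(hit) / nrow(truth), nrow(truth)))
for (g in names(res)) {
  write_probe_set(res[[g]]$probe_id[res[[g]]$selected],
                  sprintf("results/markers/%s_markers.txt", g))
}

cs <- constitutive_screen(modc)
im <- intermediate_screen(modc, min_frac_samples = 0.9)
cat(sprintf("constitutively unmodified (beta < 0.2 everywhere): %d probes\n",
            length(cs$unmodified)))
cat(sprintf("constitutively modified (beta > 0.8 everywhere): %d probes\n",
            length(cs$modified)))
cat(sprintf("intermediate (0.3-0.7 in >= 90%% of samples; imprinting-like): %d probes\n",
            length(im)))
write_probe_set(im, "results/markers/intermediate_probes.txt")

vr <- variability_rank(modc, manifest, chrom_filter = "autosomes")
data.table::fwrite(vr, "results/markers/variability_rank.tsv", sep = "\t")
cat(sprintf("variability ranking: top autosomal probe %s (SD %.3f)\n",
            vr$probe_id[1], vr$sd[1]))
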