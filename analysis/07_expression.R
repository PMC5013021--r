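#!/usr/bin/env Rscript
# Stage 7 — relative expression of candidate genes (2^-ddCt).
#
# Normalizes target-gene Ct to the reference gene, calibrates to the young
# control group, and tests group differences with one-way ANOVA + Tukey
# HSD on the animal-level dCt values.

source("analysis/00_config.R")

ct <- generate_ct_table(CONFIG)
rows <- list()
for (gene in names(CONFIG$expression$target_folds)) {
  res <- expression_analysis(ct, gene, CONFIG$expression$ref_gene,
                             calibrator_group = CONFIG$control_group)
  cat(sprintf("\n== %s (vs %s, calibrator %s) ==\n", gene,
              CONFIG$expression$ref_gene, CONFIG$control_group))
  print(res$groups[, .(group, mean_fold = round(mean_fold, 2),
                       sem_fold = round(sem_fold, 3), n)])
  cat(sprintf("ANOVA on dCt: F = %.1f, p = %.2g\n",
              res$anova$anova_f, res$anova$anova_p))
  sig <- res$anova$tukey[p_adj < 0.05]
  if (nrow(sig))
    cat("Tukey HSD pairs with p < 0.05:",
        paste(sig$comparison, collapse = ", "), "\n")
  rows[[gene]] <- cbind(gene = gene, res$groups)
}
data.table::fwrite(data.table::rbindlist(rows),
                   file.path(RESULTS, "expression_folds.tsv"), sep = "\t")
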