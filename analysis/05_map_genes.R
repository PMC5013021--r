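#!/usr/bin/env Rscript
# Stage 5 — gene mapping and cross-comparison overlap.
#
# Maps testable loci to genes via the [TSS - 10 kb, TES + 10 kb) window,
# flags differentially methylated genes, and intersects candidate loci and
# genes across the three comparisons.

source("analysis/00_config.R")

d <- study_data()
m <- study_matrix(d)
genes <- generate_annotation(CONFIG, d$loci)
win <- build_windows(genes)

cand_loci <- list(); dm_genes <- list()
for (g in setdiff(names(CONFIG$groups), CONFIG$control_group)) {
  cmp <- study_comparison(g, m)
  assoc <- map_loci(cmp$results[testable == TRUE,
                                .(locus_id, chrom, start, end)], win)
  cand <- cmp$results[candidate == TRUE, locus_id]
  gsum <- gene_dm_summary(assoc, cand)
  data.table::fwrite(gsum, file.path(RESULTS,
                                     sprintf("gene_summary_%s.tsv", g)),
                     sep = "\t")
  cand_loci[[g]] <- cand
  dm_genes[[g]] <- gsum[differentially_methylated == TRUE, gene_id]
  cat(sprintf("Con/%s: %d candidate loci map to %d differentially methylated gene(s)\n",
              g, length(cand), length(dm_genes[[g]])))
}

ol <- overlap_summary(cand_loci)
og <- overlap_summary(dm_genes)
cat("\nCandidate locus overlaps (pairwise):\n"); print(ol$pairwise)
cat("Loci shared by all three comparisons:", ol$all_n, "\n")
cat("\nDM gene overlaps (pairwise):\n"); print(og$pairwise)
cat("Genes shared by all three comparisons:", og$all_n, "\n")
data.table::fwrite(ol$pairwise, file.path(RESULTS, "overlap_loci.tsv"),
                   sep = "\t")
data.table::fwrite(og$pairwise, file.path(RESULTS, "overlap_genes.tsv"),
                   sep = "\t")
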