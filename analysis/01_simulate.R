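#!/usr/bin/env Rscript
# Stage 1 — simulate the HELP-tagging study.
#
# Generates the locus track, two-enzyme tag counts with ground truth,
# gene models with HpaII-site counts, gene sets and the qPCR Ct table,
# and writes them as plain-text files under results/data/.

source("analysis/00_config.R")
outdir <- file.path(RESULTS, "data")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

d <- study_data()
genes <- generate_annotation(CONFIG, d$loci)
sets <- generate_gene_sets(CONFIG, genes)
ct <- generate_ct_table(CONFIG)

write_counts_tsv(d$counts, file.path(outdir, "counts.tsv"))
data.table::fwrite(d$truth, file.path(outdir, "truth.tsv"), sep = "\t")
write_loci_bed(d$loci, file.path(outdir, "loci.bed"))
write_genes_gtf(genes, file.path(outdir, "genes.gtf"))
write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
data.table::fwrite(ct, file.path(outdir, "ct_table.csv"))

cat("Simulated", nrow(d$loci), "loci over", CONFIG$n_chromosomes,
    "chromosomes (mean gap",
    round(mean(diff(d$loci$start[d$loci$chrom == "chr1"]))), "bp)\n")
cat("Spiked (locus, group) pairs:", nrow(d$truth), "— per group:\n")
print(d$truth[, .N, by = .(group, direction)])
cat("DMR truth blocks:", length(unique(na.omit(d$truth$dmr_block))), "\n")
cat("Genes:", nrow(genes), "— HpaII sites per gene: median",
    median(genes$n_hpaii_sites), ", max", max(genes$n_hpaii_sites), "\n")
cat("Outputs in", outdir, "\n")
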