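# helptagdm

Differential DNA-methylation analysis for HELP-tagging data — a two-enzyme
(HpaII/MspI) restriction-and-sequencing assay — implemented as an R package
plus a numbered analysis workflow.

## The problem

HELP-tagging interrogates cytosine methylation at CCGG sites genome-wide:
methylation-sensitive *HpaII* and methylation-insensitive *MspI* digests are
sequenced and tag counts compared per locus. The analysis questions are the
classic ones of developmental-programming epigenomics: given liver samples
from young control animals, young animals exposed *in utero* to maternal
under- or overnutrition, and aged animals, which loci change methylation,
do exposures shift methylation in the same direction as aging, which
regions and genes are affected, which pathways are over-represented once
assay bias is removed, and do candidate genes change expression?

The package provides each stage as a tested function:

| Stage | Functions |
|---|---|
| Synthetic study generator (with ground truth) | `sim_config()`, `generate_loci()`, `generate_counts()`, `generate_annotation()`, `generate_gene_sets()`, `generate_ct_table()` |
| Scoring and QC | `compute_scores()`, `compute_confidence()`, `filter_loci()`, `sample_qc()` |
| Differential testing | `loci_t_test()`, `select_candidates()`, `direction_enrichment()`, `permutation_correction()`, `power_simulation()`, `power_analytic()`, `cluster_loci()` |
| DMRs | `find_dmrs()` (and the test-only `dmr_oracle()`) |
| Gene mapping | `build_windows()`, `map_loci()`, `map_dmrs()`, `gene_dm_summary()` |
| Set enrichment | `compute_bias_weights()`, `weighted_enrichment()`, `enrich_all()` |
| Expression | `ddct_fold_change()`, `anova_tukey()`, `expression_analysis()` |
| Orchestration | `run_pipeline()`, `overlap_summary()` |

## The core statistics

Per-locus methylation score (0 = fully methylated, 100 = unmethylated):

    score_is = 100 * min(1, (h_is / H_s) / (r_i / R))

with `h` the HpaII count, `H` the sample depth normalizer, `r` the pooled
MspI reference. Candidate loci pass a pooled two-sided t-test against
control with **|Δ| > 30** score units and **p < 0.005** (Δ < 0 =
hypermethylation). Correction uses 400 label permutations pooled into one
null p distribution (significant = below its 2.5th percentile). DMRs are
maximal runs of ≥ 4 consecutive same-direction candidate loci within 10 kb
of each other. Loci map to genes in the window [TSS − 10 kb, TES + 10 kb)
in transcription orientation. Set enrichment draws gene samples weighted
by per-gene HpaII-site-count bias (quantile-binned empirical DM rates) and
reports add-one sampling p-values. Expression uses 2^−ΔΔCt against a
reference gene and calibrator group, tested by ANOVA + Tukey HSD.

The detection-power calibration behind the candidate gates, from the
noncentral-t closed form (`power_analytic()`): 77.5% for a balanced n=5
design and 85.0% for the study's actual 5-vs-6 group sizes (SD 10, effect
30, α = 0.005).

## Worked example

```r
library(helptagdm)

cfg  <- sim_config(seed = 101)            # the default study conditions
loci <- generate_loci(cfg)                # ~100k loci, mean gap 2 kb
sim  <- generate_counts(cfg, loci)        # HpaII/MspI counts + truth
mat  <- compute_scores(sim$counts)
conf <- compute_confidence(sim$counts)

fm  <- filter_loci(mat, conf,
                   samples = mat$samples[group %in% c("Con", "UN"), sample])
res <- loci_t_test(fm, "Con", "UN")
nrow(res[candidate == TRUE])
direction_enrichment(res)$odds_ratio
```

On this seed the run prints: 100,445 simulated loci; 39,422 survive the
confidence filter for the Con/UN comparison; 167 candidate loci pass the
gates, 166 hypermethylated vs 1 hypomethylated (direction odds ratio 165,
Fisher p ≈ 2e−48) — the undernutrition exposure is simulated as
hypermethylating, and the test recovers that direction. Sensitivity at the
spiked loci is 0.87 against an analytic power of 0.85 for the 5v6 design.
The same workflow, stage by stage with commentary, lives in
`analysis/01_simulate.R` … `analysis/07_expression.R`, each writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # counts, truth, genes, sets, Ct table
Rscript analysis/03_differential.R
Rscript analysis/07_expression.R # e.g. Ncor2 folds 1 / 11.5 / 4.1 / 6.5
                                 # (Con / UN / ON / Old), ANOVA p = 6.5e-20
```

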