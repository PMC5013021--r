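test_that("locus spacing matches the configured mean", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2.2e7,
                    mean_locus_spacing = 2000, seed = 3)
  loci <- generate_loci(cfg)
  expect_gt(nrow(loci), 9000)
  gaps <- diff(loci$start)
  expect_lt(abs(mean(gaps) - 2000) / 2000, 0.05)
  expect_false(is.unsorted(loci$start))
  expect_true(all(loci$start < cfg$chromosome_length))
})

test_that("degenerate and error cases of locus generation", {
  cfg1 <- sim_config(n_chromosomes = 1, chromosome_length = 1e5,
                     n_loci = 1, seed = 5)
  one <- generate_loci(cfg1)
  expect_identical(nrow(one), 1L)
  expect_lt(one$start, cfg1$chromosome_length)

  cfg_bad <- sim_config(n_chromosomes = 1, chromosome_length = 1e4,
                        n_loci = 1000, seed = 5)
  expect_error(generate_loci(cfg_bad), "too short")
  expect_error(sim_config(mean_locus_spacing = -5), "positive")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 9)
  l1 <- generate_loci(cfg); l2 <- generate_loci(cfg)
  expect_identical(l1, l2)
  s1 <- generate_counts(cfg, l1); s2 <- generate_counts(cfg, l1)
  expect_identical(s1$counts$hpaii, s2$counts$hpaii)
  expect_identical(s1$truth, s2$truth)
  g1 <- generate_annotation(cfg, l1); g2 <- generate_annotation(cfg, l1)
  expect_identical(g1, g2)
  p1 <- file.path(tempdir(), "g1.gtf"); p2 <- file.path(tempdir(), "g2.gtf")
  write_genes_gtf(g1, p1); write_genes_gtf(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(generate_ct_table(cfg), generate_ct_table(cfg))
})

test_that("null configuration yields an empty truth table", {
  cfg <- small_config(seed = 2, frac_differential = 0,
                      n_shared_differential = 0, n_dmr_blocks = 0)
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  expect_identical(nrow(sim$truth), 0L)
  expect_true(all(sim$counts$hpaii >= 0) && all(sim$counts$mspi >= 0))
  expect_error(sim_config(frac_differential = 1.5), "\\[0, 1\\]")
})

test_that("spiked effects are recovered in realized group means", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 2e7, seed = 11)
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  mat <- compute_scores(sim$counts)
  grp <- mat$samples
  con <- rowMeans(mat$scores[, grp[group == "Con", sample]], na.rm = TRUE)
  un <- rowMeans(mat$scores[, grp[group == "UN", sample]], na.rm = TRUE)
  hyper <- sim$truth[group == "UN" & true_delta < 0, locus_id]
  # hypermethylation in UN: control minus exposed ~ +30; boundary clipping
  # at the top of the score scale shaves under a point off
  expect_lt(abs(mean(con[hyper] - un[hyper]) - 30), 2)
  # truth consistency: every spiked locus moved at least half the effect
  all_un <- sim$truth[group == "UN"]
  realized <- abs(con[all_un$locus_id] - un[all_un$locus_id])
  expect_gt(mean(realized >= 15), 0.98)
})

test_that("realized per-group score SD stays near the configured value", {
  cfg <- small_config(seed = 13)
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  mat <- compute_scores(sim$counts)
  null_ids <- setdiff(rownames(mat$scores), unique(sim$truth$locus_id))
  sc <- mat$scores[null_ids, ]
  for (g in unique(mat$samples$group)) {
    cols <- mat$samples[group == g, sample]
    sds <- apply(sc[, cols], 1, stats::sd, na.rm = TRUE)
    m <- mean(sds, na.rm = TRUE)
    expect_gt(m, 0.8 * cfg$score_sd)
    expect_lt(m, 1.2 * cfg$score_sd)
  }
  expect_true(all(mat$scores >= 0 & mat$scores <= 100, na.rm = TRUE))
})

test_that("zero-inflated sample has the most zero-HpaII loci and is flagged", {
  cfg <- small_config(seed = 4, zero_inflation_sample = "ON2")
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  zf <- colMeans(sim$counts$hpaii == 0)
  expect_identical(names(which.max(zf)), "ON2")
  expect_true(all(zf["ON2"] > zf[names(zf) != "ON2"]))
  qc <- sample_qc(compute_scores(sim$counts))
  expect_true(qc[sample == "ON2", flagged])
  expect_identical(qc[flagged == TRUE, sample], "ON2")
})

test_that("DMR truth blocks are contiguous, tight and fully spiked", {
  cfg <- small_config(seed = 21)
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  blocks <- sim$truth[!is.na(dmr_block)]
  expect_equal(length(unique(blocks$dmr_block)),
               3 * cfg$n_dmr_blocks)  # three exposed groups
  for (b in unique(blocks$dmr_block)) {
    ids <- blocks[dmr_block == b, locus_id]
    expect_gte(length(ids), 4)
    pos <- loci[locus_id %in% ids][order(start)]
    expect_identical(length(unique(pos$chrom)), 1L)
    expect_true(all(diff(pos$start) <= 10000 + 2))
    # one direction per block
    expect_identical(length(unique(blocks[dmr_block == b, direction])), 1L)
  }
})

test_that("per-gene HpaII-site counts equal a brute-force interval scan", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 6e6,
                    n_genes = 80, seed = 17)
  loci <- generate_loci(cfg)
  genes <- generate_annotation(cfg, loci)
  win <- build_windows(genes)
  brute <- vapply(seq_len(nrow(win)), function(i) {
    sum(loci$chrom == win$chrom[i] &
          loci$end > win$window_start[i] &
          loci$start < win$window_end[i])
  }, numeric(1))
  expect_equal(genes$n_hpaii_sites, as.integer(brute))
  # site counts span at least an order of magnitude
  pos <- genes$n_hpaii_sites[genes$n_hpaii_sites > 0]
  expect_gte(max(pos) / min(pos), 10)
  # strand sanity: tss upstream of tes in transcription orientation
  expect_true(all(genes[strand == "+", tss < tes]))
  expect_true(all(genes[strand == "-", tss > tes]))
})

test_that("Ct tables have triplicates and recover configured folds", {
  cfg <- small_config(seed = 6)
  ct <- generate_ct_table(cfg)
  reps <- ct[, .N, by = .(animal_id, gene)]
  expect_true(all(reps$N == 3))
  # fold = 1 everywhere: mean ddct ~ 0
  cfg_null <- small_config(seed = 6, expression = utils::modifyList(
    cfg$expression, list(target_folds = list(Flat = c(Con = 1, UN = 1,
                                                      ON = 1, Old = 1)))))
  ct0 <- generate_ct_table(cfg_null)
  f0 <- ddct_fold_change(ct0, "Flat", cfg$expression$ref_gene, "Con")
  expect_lt(abs(mean(f0$per_animal$ddct)), 0.25)
  # configured fold 4 in ON recovered within noise
  f <- ddct_fold_change(ct, "Ncor2", "Rps3", "Con")
  on <- f$groups[group == "ON"]
  expect_lt(abs(on$mean_fold - 4), 4 * on$sem_fold + 0.5)
})
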