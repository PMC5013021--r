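test_that("methylation scores follow the density-ratio formula", {
  # 3 loci, 2 samples; supplied depth factors; MspI reference = pooled rows
  hp <- matrix(c(0, 50, 100,
                 0, 25, 200), ncol = 2)
  ms <- matrix(c(100, 100, 100,
                 100, 100, 100), ncol = 2)
  cnt <- make_counts(hp, ms, hpaii_total = c(200, 200),
                     mspi_total = c(300, 300))
  m <- compute_scores(cnt)
  # ref density = 200/600 = 1/3 per locus
  # s1: 0 -> 0 (fully methylated); 50/200/(1/3) = 0.75 -> 75; 100/200 -> 100
  expect_equal(unname(m$scores[, 1]), c(0, 75, 100))
  # s2: 0; 25/200 = .125 -> 37.5; 200/200 = 1 -> capped at 100
  expect_equal(unname(m$scores[, 2]), c(0, 37.5, 100))
})

test_that("half the reference density scores 50; zero reference is NA", {
  hp <- matrix(c(50, 10), ncol = 1)
  ms <- matrix(c(100, 0), ncol = 1)
  cnt <- make_counts(hp, ms, hpaii_total = 100, mspi_total = 100)
  m <- compute_scores(cnt)
  expect_equal(unname(m$scores[1, 1]), 50)  # 50/100 vs 100/100
  expect_true(is.na(m$scores[2, 1]))        # unscorable
  bad <- make_counts(hp, ms, hpaii_total = c(0), mspi_total = 100)
  expect_error(compute_scores(bad), "library total")
})

test_that("confidence is monotone in both counts with a floor at zero", {
  hp <- matrix(c(0, 5, 5, 50), ncol = 1)
  ms <- matrix(c(0, 1, 20, 20), ncol = 1)
  cnt <- make_counts(hp, ms, hpaii_total = 60, mspi_total = 41)
  conf <- compute_confidence(cnt)
  expect_identical(unname(which.min(conf)), 1L)   # both counts zero
  expect_equal(unname(conf[1, 1]), 0)
  # hand computation: (ref/ref_total) * mean_depth * (1 - exp(-(h + m)))
  ref <- rowSums(cnt$mspi)
  hand <- (ref / sum(ref)) * 60 * (1 - exp(-(hp[, 1] + ms[, 1])))
  expect_equal(unname(conf[, 1]), hand)
  # doubling mspi never decreases confidence anywhere
  cnt2 <- make_counts(hp, ms * 2L, hpaii_total = 60, mspi_total = 82)
  expect_true(all(compute_confidence(cnt2) >= conf - 1e-12))
})

test_that("confidence filter drops under-covered loci and is idempotent", {
  set.seed(1)
  hp <- matrix(rpois(12 * 4, 40), 12, 4)
  ms <- matrix(rpois(12 * 4, 40), 12, 4)
  hp[3, ] <- c(0, 1, 0, 0); ms[3, ] <- c(1, 0, 0, 1)  # under-covered locus
  cnt <- make_counts(hp, ms, hpaii_total = colSums(hp),
                     mspi_total = colSums(ms))
  mat <- compute_scores(cnt)
  conf <- compute_confidence(cnt)
  f <- filter_loci(mat, conf)
  expect_false("L00003" %in% f$loci$locus_id)
  expect_identical(attr(f, "filter_report")$n_retained, nrow(f$loci))
  # adaptive per-locus rule: exactly the under-covered locus goes
  fl <- filter_loci(mat, conf, mode = "per_locus")
  expect_identical(setdiff(mat$loci$locus_id, fl$loci$locus_id), "L00003")
  # idempotent in both modes
  f2 <- filter_loci(f, conf)
  expect_identical(f$loci, f2$loci)
  fp <- filter_loci(mat, conf, mode = "per_locus")
  fp2 <- filter_loci(fp, conf, mode = "per_locus")
  expect_identical(fp$loci, fp2$loci)
})

test_that("equal confidences filter nothing; thresholds act monotonically", {
  hp <- matrix(10, 6, 3); ms <- matrix(10, 6, 3)
  cnt <- make_counts(hp, ms, hpaii_total = rep(60, 3),
                     mspi_total = rep(60, 3))
  mat <- compute_scores(cnt)
  conf <- compute_confidence(cnt)
  expect_identical(nrow(filter_loci(mat, conf)$loci), 6L)
  expect_identical(nrow(filter_loci(mat, conf, mode = "per_locus")$loci), 6L)
  # raising the factor never increases retained loci
  cfg <- small_config(seed = 31)
  sim <- generate_counts(cfg, generate_loci(cfg))
  m2 <- compute_scores(sim$counts)
  c2 <- compute_confidence(sim$counts)
  kept <- vapply(c(0.25, 0.5, 1, 1.5), function(f)
    nrow(filter_loci(m2, c2, factor = f)$loci), numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_error(filter_loci(m2, c2, factor = 1e6), "empty")
})

test_that("sample QC flags nothing on clean data and warns when underpowered", {
  cfg <- small_config(seed = 8)
  sim <- generate_counts(cfg, generate_loci(cfg))
  qc <- sample_qc(compute_scores(sim$counts))
  expect_identical(sum(qc$flagged), 0L)
  # identical zero fractions: nothing flagged
  m <- make_matrix(matrix(c(0, 50, 80), 3, 4), rep(c("a", "b"), each = 2))
  expect_identical(sum(sample_qc(m)$flagged), 0L)
  m2 <- make_matrix(matrix(50, 3, 2), c("a", "b"))
  expect_warning(qc2 <- sample_qc(m2), "fewer than 3")
  expect_false(any(qc2$flagged))
})
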