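mk_results <- function(start, candidate, direction = "hyper",
                       testable = TRUE, chrom = "chr1", p = 1e-4) {
  n <- length(start)
  data.table::data.table(
    locus_id = sprintf("L%03d", seq_len(n)), chrom = chrom,
    start = start, end = start + 2,
    delta = ifelse(rep(direction, length.out = n) == "hyper", -40, 40),
    t = 0, df = 9, p = rep(p, length.out = n),
    testable = rep(testable, length.out = n),
    candidate = candidate,
    direction = rep(direction, length.out = n))
}

test_that("a tight same-direction run of four candidates is one DMR", {
  r <- mk_results(c(1000, 3000, 5000, 7000), candidate = TRUE)
  d <- find_dmrs(r)
  expect_identical(nrow(d), 1L)
  expect_equal(d$start, 1000)
  expect_equal(d$end, 7002)
  expect_identical(d$n_loci, 4L)
  expect_identical(d$direction, "hyper")
  expect_identical(unlist(d$loci), r$locus_id)
})

test_that("gap, intervening-locus and direction rules break runs", {
  # 12 kb gap between 2nd and 3rd
  r1 <- mk_results(c(1000, 3000, 15000, 17000), candidate = TRUE)
  expect_identical(nrow(find_dmrs(r1)), 0L)
  # intervening testable non-candidate
  r2 <- mk_results(c(1000, 3000, 4000, 5000, 7000),
                   candidate = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(nrow(find_dmrs(r2)), 0L)
  # ... unless the run definition is relaxed to gap-only
  expect_identical(find_dmrs(r2, break_on_noncandidate = FALSE)$n_loci, 4L)
  # an untestable locus in the middle does not break the run
  r3 <- mk_results(c(1000, 3000, 4000, 5000, 7000),
                   candidate = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                   testable = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(find_dmrs(r3)$n_loci, 4L)
  # direction flip splits the run
  r4 <- mk_results(seq(1000, by = 2000, length.out = 8), candidate = TRUE,
                   direction = c(rep("hyper", 4), rep("hypo", 4)))
  d4 <- find_dmrs(r4)
  expect_identical(nrow(d4), 2L)
  expect_identical(d4$direction, c("hyper", "hypo"))
  expect_identical(nrow(find_dmrs(r4, require_direction = FALSE)), 1L)
})

test_that("unsorted input is an error, never silently re-sorted", {
  r <- mk_results(c(3000, 1000, 5000, 7000), candidate = TRUE)
  expect_error(find_dmrs(r), "sorted")
  expect_error(dmr_oracle(r), "sorted")
})

test_that("hand-enumerated oracle cases", {
  # all 12 loci candidates at uniform 2 kb spacing: one DMR of 12
  r <- mk_results(seq(1000, by = 2000, length.out = 12), candidate = TRUE)
  o <- dmr_oracle(r)
  expect_identical(nrow(o), 1L)
  expect_identical(o$n_loci, 12L)
  # empty candidate set
  r0 <- mk_results(c(1000, 3000), candidate = FALSE)
  expect_identical(nrow(dmr_oracle(r0)), 0L)
})

test_that("find_dmrs agrees with the exhaustive oracle on random fixtures", {
  for (s in 1:250) {
    f <- random_results_fixture(s)
    a <- find_dmrs(f, min_loci = 3)
    b <- dmr_oracle(f, min_loci = 3)
    expect_true(dmr_tables_equal(a, b), label = paste("fixture", s))
  }
})

test_that("strongly spiked blocks are recovered end to end", {
  # effect well clear of the 30-point gate so block members gate reliably;
  # this exercises the caller on generated data, where the study-default
  # effect (exactly at the gate) leaves most blocks partially gated
  cfg <- small_config(seed = 57, effect_size = 50, n_dmr_blocks = 4,
                      frac_differential = 0.005)
  loci <- generate_loci(cfg)
  sim <- generate_counts(cfg, loci)
  mat <- compute_scores(sim$counts)
  n_gated <- 0
  for (g in c("UN", "Old")) {
    res <- loci_t_test(mat, "Con", g)
    dmrs <- find_dmrs(res)
    called <- unlist(dmrs$loci)
    blocks <- sim$truth[group == g & !is.na(dmr_block)]
    for (b in unique(blocks$dmr_block)) {
      sub <- res[locus_id %in% blocks[dmr_block == b, locus_id] &
                   testable == TRUE]
      if (nrow(sub) >= 4 && all(sub$candidate)) {
        n_gated <- n_gated + 1
        expect_true(all(sub$locus_id %in% called), label = b)
      }
    }
  }
  expect_gte(n_gated, 4)  # the check must not be vacuous
})

test_that("tightening parameters never increases the DMR count", {
  for (s in 1:40) {
    f <- random_results_fixture(s + 500, cand_rate = 0.6)
    n_by_gap <- vapply(c(20000, 10000, 4000, 1000), function(g)
      nrow(find_dmrs(f, min_loci = 3, max_gap = g)), numeric(1))
    expect_true(all(diff(n_by_gap) <= 0))
    n_by_min <- vapply(c(3, 4, 6, 9), function(k)
      nrow(find_dmrs(f, min_loci = k)), numeric(1))
    expect_true(all(diff(n_by_min) <= 0))
  }
})
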