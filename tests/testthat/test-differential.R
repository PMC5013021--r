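test_that("pooled t-test matches the closed-form worked example", {
  m <- make_matrix(matrix(c(10, 20, 30, 40, 50, 60), nrow = 1),
                   groups = c("con", "con", "con", "exp", "exp", "exp"))
  r <- loci_t_test(m, "con", "exp")
  expect_equal(r$delta, 30)
  expect_equal(abs(r$t), 3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  expect_identical(r$direction, "hypo")
})

test_that("null and degenerate inputs are handled", {
  x <- matrix(rep(c(10, 20, 30), 2), nrow = 1)
  m <- make_matrix(x, groups = rep(c("a", "b"), each = 3))
  r <- loci_t_test(m, "a", "b")
  expect_equal(r$delta, 0)
  expect_equal(r$p, 1)
  # zero variance in both groups, equal means -> untestable
  m0 <- make_matrix(matrix(50, 1, 6), groups = rep(c("a", "b"), each = 3))
  r0 <- loci_t_test(m0, "a", "b")
  expect_false(r0$testable)
  expect_true(is.na(r0$p))
  expect_error(loci_t_test(m, "a", "nope"), "unknown group")
})

test_that("vectorized t-test agrees with stats::t.test per locus", {
  set.seed(99)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    n <- 5
    sc <- matrix(rnorm(n * (na + nb), 50, 12), n)
    m <- make_matrix(sc, groups = rep(c("a", "b"), c(na, nb)))
    r <- loci_t_test(m, "a", "b")
    for (j in seq_len(n)) {
      tt <- t.test(sc[j, (na + 1):(na + nb)], sc[j, 1:na],
                   var.equal = TRUE)
      expect_equal(r$t[j], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(r$p[j], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("candidate gates are strict and candidates sorted by p then effect", {
  res <- data.table::data.table(
    locus_id = c("a", "b", "c", "d", "e"),
    chrom = "chr1", start = 1:5 * 1000, end = 1:5 * 1000 + 2,
    delta = c(35, 29.9, 60, -40, 40), t = 1, df = 9,
    p = c(0.001, 1e-6, 0.01, 0.001, 0.004), testable = TRUE,
    candidate = FALSE,
    direction = c("hypo", "hypo", "hypo", "hyper", "hypo"))
  cand <- select_candidates(res)
  expect_identical(cand$locus_id, c("d", "a", "e"))  # p ties: |delta| desc
  expect_identical(res[candidate == TRUE, locus_id], c("a", "d", "e"))
  expect_false(res[locus_id == "b", candidate])  # delta gate
  expect_false(res[locus_id == "c", candidate])  # p gate
})

test_that("direction enrichment matches an exact hypergeometric oracle", {
  # table: candidates 30 hyper / 10 hypo; background 470 / 490
  mk <- function(nch, nco, bh, bo) data.table::data.table(
    locus_id = sprintf("L%04d", seq_len(nch + nco + bh + bo)),
    chrom = "chr1", delta = rep(c(-1, 1, -1, 1), c(nch, nco, bh, bo)),
    p = 0.5, testable = TRUE,
    candidate = rep(c(TRUE, FALSE), c(nch + nco, bh + bo)),
    direction = rep(c("hyper", "hypo", "hyper", "hypo"),
                    c(nch, nco, bh, bo)))
  de <- direction_enrichment(mk(30, 10, 470, 490))
  expect_equal(de$odds_ratio, 30 * 490 / (10 * 470), tolerance = 1e-12)
  # independent oracle: enumerate the conditional hypergeometric law
  hyper_total <- 500; n_cand <- 40; n_tot <- 1000
  k <- 0:40
  pk <- dhyper(k, hyper_total, n_tot - hyper_total, n_cand)
  p_exact <- sum(pk[pk <= dhyper(30, hyper_total, n_tot - hyper_total,
                                 n_cand) * (1 + 1e-7)])
  expect_equal(de$p_value, p_exact, tolerance = 1e-8)
  # perfectly balanced table
  de0 <- direction_enrichment(mk(20, 20, 200, 200))
  expect_equal(de0$odds_ratio, 1)
  expect_equal(de0$p_value, 1)
  # all candidates hyper, balanced background: infinite OR convention
  dei <- direction_enrichment(mk(15, 0, 200, 200))
  expect_identical(dei$odds_ratio, Inf)
  expect_lt(dei$p_value, 0.001)
  # a fully empty direction stratum degenerates to p = 1 with a warning
  expect_warning(dee <- direction_enrichment(mk(15, 0, 200, 0)),
                 "empty stratum")
  expect_equal(dee$p_value, 1)
})

test_that("permutation pools a null distribution and never promotes", {
  set.seed(5)
  n <- 2500
  grp <- rep(c("Con", "UN"), c(5, 6))
  sc <- matrix(rnorm(n * 11, 50, 10), n)
  m <- make_matrix(sc, groups = grp)
  res <- loci_t_test(m, "Con", "UN")
  pc <- permutation_correction(m, res, n_perm = 150, seed = 3)
  # pure null: ~2.5% of loci sit below the pooled 2.5th percentile
  expect_lt(abs(mean(pc$perm_frac <= 0.025) - 0.025), 0.012)
  expect_identical(sum(pc$corrected_significant & !pc$candidate), 0L)
  info <- attr(pc, "perm_info")
  expect_identical(info$n_distinct, choose(11, 5))
  expect_identical(info$n_perm, 150)
  # identity assignment reproduces the observed p-values
  p_id <- helptagdm:::perm_pvalues(sc, 1:5)  # columns: 5 Con then 6 UN
  expect_equal(p_id, res$p, tolerance = 1e-12)
})

test_that("a clearly extreme candidate survives correction", {
  set.seed(6)
  n <- 400
  grp <- rep(c("a", "b"), each = 4)
  sc <- matrix(rnorm(n * 8, 50, 8), n)
  sc[1, grp == "b"] <- sc[1, grp == "b"] + 60   # far beyond any permuted p
  m <- make_matrix(sc, groups = grp)
  res <- loci_t_test(m, "a", "b")
  expect_true(res$candidate[1])
  expect_message(pc <- permutation_correction(m, res, n_perm = 100,
                                              seed = 2),
                 "with replacement")  # C(8,4)=70 distinct assignments
  expect_true(pc$corrected_significant[1])
})

test_that("simulated power matches the noncentral-t oracle", {
  # oracle values frozen from the closed form: df=8, ncp=4.7434 -> 0.77470;
  # df=9 (5 vs 6), ncp=4.9548 -> 0.84985
  expect_equal(power_analytic(5, 5, 10, 30, 0.005), 0.7747047,
               tolerance = 1e-6)
  expect_equal(power_analytic(5, 6, 10, 30, 0.005), 0.8498457,
               tolerance = 1e-6)
  ps <- power_simulation(n_per_group = 5, sd = 10, delta = 30,
                         alpha = 0.005, n_sim = 1000, seed = 42)
  expect_equal(ps$mc_se, sqrt(ps$power * (1 - ps$power) / 1000))
  expect_lt(abs(ps$power - 0.7747047), 3 * ps$mc_se)
  # null case: rejection at the nominal level
  p0 <- power_simulation(delta = 0, n_sim = 2000, seed = 1)
  expect_lt(abs(p0$power - 0.005), 3 * sqrt(0.005 * 0.995 / 2000))
  # saturated effect
  expect_equal(power_simulation(delta = 30, sd = 1, n_sim = 500,
                                seed = 2)$power, 1)
  expect_error(power_simulation(n_sim = 10), ">= 100")
})

test_that("hierarchical clustering separates groups and orders leaves", {
  prof_a <- rep(c(10, 90), 10); prof_b <- rep(c(80, 20), 10)
  sc <- cbind(prof_a, prof_a, prof_a, prof_b, prof_b, prof_b) +
    matrix(rnorm(120, 0, 0.5), 20)
  colnames(sc) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- make_matrix(sc, groups = rep(c("a", "b"), each = 3))
  cl <- cluster_loci(m, by = "samples")
  k2 <- stats::cutree(cl$hclust, k = 2)
  expect_identical(length(unique(k2[c("a1", "a2", "a3")])), 1L)
  expect_identical(length(unique(k2[c("b1", "b2", "b3")])), 1L)
  expect_false(k2[["a1"]] == k2[["b1"]])
  expect_setequal(cl$order, colnames(sc))
  # identical samples merge at height zero
  m0 <- make_matrix(matrix(50, 5, 4), groups = rep(c("a", "b"), 2))
  expect_true(all(cluster_loci(m0, by = "samples")$hclust$height == 0))
})
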