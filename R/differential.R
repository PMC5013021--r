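# Vectorized row-wise group statistics with NA handling.
row_group_stats <- function(m) {
  ok <- !is.na(m)
  n <- rowSums(ok)
  s <- rowSums(m, na.rm = TRUE)
  mean <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(m^2, na.rm = TRUE)
  var <- ifelse(n > 1, (ss - n * mean^2) / (n - 1), NA_real_)
  var <- pmax(var, 0)  # guard tiny negatives from cancellation
  list(n = n, mean = mean, var = var)
}

#' Per-locus two-group pooled t-test
#'
#' Equal-variance (pooled) two-sided t-test at every locus, vectorized over
#' the matrix, comparing a control group against an exposed group. `delta`
#' is exposed mean minus control mean on the 0--100 score scale, so
#' `delta < 0` is hypermethylation (toward 0 = methylated) and `delta > 0`
#' hypomethylation. Loci with fewer than 2 non-missing values in either
#' group, or with zero pooled variance and equal means, are reported
#' untestable rather than dropped. Welch's unequal-variance test is
#' available via `var_equal = FALSE`.
#'
#' Candidate loci ("loci of interest") are flagged with the standard gates
#' |delta| > 30 and p < 0.005 (strict inequalities); see
#' [select_candidates()] to re-gate.
#'
#' @param matrix a `meth_matrix`.
#' @param control control group label.
#' @param exposed exposed group label.
#' @param min_abs_delta,max_p candidate gates.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) test.
#' @return data.table: `locus_id`, `chrom`, `start`, `end`, `n_control`,
#'   `n_exposed`, `mean_control`, `mean_exposed`, `delta`, `t`, `df`, `p`,
#'   `testable`, `candidate`, `direction` (`hyper`/`hypo`, NA at delta 0).
#' @export
loci_t_test <- function(matrix, control, exposed,
                        min_abs_delta = 30, max_p = 0.005,
                        var_equal = TRUE) {
  stopifnot(inherits(matrix, "meth_matrix"))
  grp <- matrix$samples
  for (g in c(control, exposed))
    if (!g %in% grp$group) stop("unknown group label: ", g)
  sa <- grp[group == control, sample]
  sb <- grp[group == exposed, sample]
  a <- row_group_stats(matrix$scores[, sa, drop = FALSE])
  b <- row_group_stats(matrix$scores[, sb, drop = FALSE])
  delta <- b$mean - a$mean
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$var / a$n; vb <- b$var / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tstat <- delta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero pooled variance: p -> 0 if means differ, untestable if equal
  degen <- !is.na(se) & se == 0
  p[degen & delta != 0] <- 0
  tstat[degen & delta != 0] <- Inf * sign(delta[degen & delta != 0])
  testable <- a$n >= 2 & b$n >= 2 & !(degen & delta == 0)
  p[!testable] <- NA_real_
  res <- data.table::data.table(
    locus_id = matrix$loci$locus_id, chrom = matrix$loci$chrom,
    start = matrix$loci$start, end = matrix$loci$end,
    n_control = a$n, n_exposed = b$n,
    mean_control = a$mean, mean_exposed = b$mean,
    delta = delta, t = tstat, df = df, p = p, testable = testable)
  res[, candidate := testable & abs(delta) > min_abs_delta & p < max_p]
  res[is.na(candidate), candidate := FALSE]
  res[, direction := data.table::fifelse(
    delta < 0, "hyper", data.table::fifelse(delta > 0, "hypo",
                                            NA_character_))]
  attr(res, "comparison") <- c(control = control, exposed = exposed)
  res[]
}

#' Re-gate and rank candidate loci
#'
#' Applies the candidate gates (strict inequalities: |delta| >
#' `min_abs_delta` and p < `max_p`) to a differential result table and
#' returns the candidates sorted by p, ties broken by decreasing |delta|.
#' The `candidate` column of `results` is updated in place.
#'
#' @param results table from [loci_t_test()].
#' @param min_abs_delta minimum absolute score difference.
#' @param max_p maximum p-value.
#' @return data.table of candidate rows, sorted.
#' @export
select_candidates <- function(results, min_abs_delta = 30, max_p = 0.005) {
  results[, candidate := testable & abs(delta) > min_abs_delta & p < max_p]
  results[is.na(candidate), candidate := FALSE]
  cand <- results[candidate == TRUE]
  cand[order(p, -abs(delta))]
}

#' Direction enrichment among candidate loci
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' {candidate, non-candidate} x {hyper (delta < 0), hypo (delta > 0)},
#' asking whether candidate loci are enriched for one direction of change
#' relative to the testable background. Zero-delta loci are excluded. The
#' reported odds ratio is the sample cross-product ratio
#' (cand_hyper * bg_hypo) / (cand_hypo * bg_hyper); an empty cell yields
#' `Inf` or 0 by that convention. With an empty stratum the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param results table from [loci_t_test()] with candidate flags.
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
direction_enrichment <- function(results) {
  r <- results[testable == TRUE & !is.na(direction)]
  if (nrow(r[candidate == TRUE]) < 1 || nrow(r[candidate == FALSE]) < 1)
    stop("need at least one candidate and one non-candidate locus")
  tab <- matrix(c(sum(r$candidate & r$direction == "hyper"),
                  sum(!r$candidate & r$direction == "hyper"),
                  sum(r$candidate & r$direction == "hypo"),
                  sum(!r$candidate & r$direction == "hypo")),
                nrow = 2,
                dimnames = list(c("candidate", "background"),
                                c("hyper", "hypo")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty stratum in direction table; p set to 1")
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    return(list(odds_ratio = or, p_value = 1, table = tab))
  }
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, table = tab)
}

# p-values for one label assignment; `sa` indexes the pseudo-control
# columns within the comparison submatrix.
perm_pvalues <- function(scores, sa_idx, var_equal = TRUE) {
  a <- row_group_stats(scores[, sa_idx, drop = FALSE])
  b <- row_group_stats(scores[, -sa_idx, drop = FALSE])
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  tstat <- (b$mean - a$mean) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!(a$n >= 2 & b$n >= 2) | (se == 0)] <- NA_real_
  p
}

#' Permutation correction of candidate loci
#'
#' Permutes the two comparison groups' labels `n_perm` times, pools the
#' per-locus permuted p-values into a single null distribution, and keeps a
#' candidate as significant after correction iff its observed p-value is at
#' or below the 2.5th percentile of that pooled distribution (i.e. more
#' extreme than 97.5% of permuted p-values; two-tailed 0.05). When the
#' number of distinct label assignments is tractable they are enumerated
#' and sampled without replacement; if fewer distinct assignments exist
#' than `n_perm`, sampling falls back to with-replacement and the distinct
#' count is recorded. A non-candidate locus is never promoted.
#'
#' @param matrix a `meth_matrix` (same one the results were computed from).
#' @param results table from [loci_t_test()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return copy of `results` with `corrected_significant` and `perm_frac`
#'   (fraction of pooled permuted p-values <= observed p) columns; the
#'   `perm_info` attribute records n_perm, distinct-assignment count, the
#'   pooled 2.5th-percentile p threshold and the seed.
#' @export
permutation_correction <- function(matrix, results, n_perm = 400,
                                   seed = 1L) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  comp <- attr(results, "comparison")
  if (is.null(comp)) stop("results lack a comparison attribute")
  grp <- matrix$samples
  sa <- grp[group == comp[["control"]], sample]
  sb <- grp[group == comp[["exposed"]], sample]
  sc <- matrix$scores[results$locus_id, c(sa, sb), drop = FALSE]
  n_tot <- length(sa) + length(sb)
  n_a <- length(sa)
  n_distinct <- choose(n_tot, n_a)
  if (n_distinct < 2) stop("fewer than 2 distinguishable permutations")
  set.seed(seed)
  if (n_distinct <= 5000) {
    combos <- utils::combn(n_tot, n_a)
    if (n_distinct >= n_perm) {
      pick <- sample.int(ncol(combos), n_perm)
    } else {
      message("only ", n_distinct, " distinct assignments; sampling with ",
              "replacement")
      pick <- sample.int(ncol(combos), n_perm, replace = TRUE)
    }
    assign_list <- lapply(pick, function(j) combos[, j])
  } else {
    assign_list <- lapply(seq_len(n_perm),
                          function(i) sample.int(n_tot, n_a))
  }
  obs <- results$p
  cnt <- numeric(length(obs))
  n_pooled <- 0
  all_perm_small <- numeric(0)  # running reservoir of smallest permuted p's
  for (idx in assign_list) {
    pp <- perm_pvalues(sc, idx)
    pp <- pp[!is.na(pp)]
    n_pooled <- n_pooled + length(pp)
    sp <- sort(pp)
    cnt <- cnt + findInterval(obs, sp)
    # keep enough of the left tail to recover the 2.5th percentile exactly
    all_perm_small <- sort(c(all_perm_small, sp[seq_len(
      min(length(sp), max(100, ceiling(0.10 * length(pp)))))]))
  }
  frac <- cnt / n_pooled
  thr_idx <- max(1, floor(0.025 * n_pooled))
  thr <- if (thr_idx <= length(all_perm_small)) all_perm_small[thr_idx]
         else stats::quantile(all_perm_small, 1, names = FALSE)
  out <- data.table::copy(results)
  out[, perm_frac := frac]
  out[, corrected_significant := candidate & !is.na(p) & frac <= 0.025]
  attr(out, "comparison") <- comp
  attr(out, "perm_info") <- list(n_perm = n_perm, n_distinct = n_distinct,
                                 p_threshold = thr, seed = seed,
                                 n_pooled = n_pooled)
  out[]
}

#' Analytic power of the pooled two-sample t-test
#'
#' Closed-form power from the noncentral-t distribution with
#' df = n1 + n2 - 2 and noncentrality delta / (sd * sqrt(1/n1 + 1/n2)).
#'
#' @param n1,n2 group sizes.
#' @param sd common within-group SD (score units).
#' @param delta true mean difference (score units).
#' @param alpha two-sided significance level.
#' @return power (fraction).
#' @export
power_analytic <- function(n1 = 5, n2 = n1, sd = 10, delta = 30,
                           alpha = 0.005) {
  df <- n1 + n2 - 2
  ncp <- delta / (sd * sqrt(1 / n1 + 1 / n2))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Simulation-based power of the candidate p-gate
#'
#' Simulates `n_sim` two-group normal datasets with a true mean difference
#' of `delta` and common SD `sd`, applies the pooled two-sided t-test, and
#' reports the fraction rejected at level `alpha` — the detection power of
#' the per-locus test at the study's calibration point (n = 5 per group,
#' SD = 10 score units, difference = 30, p < 0.005).
#'
#' @param n_per_group samples in the first group.
#' @param sd common within-group SD.
#' @param delta true mean difference.
#' @param alpha two-sided level.
#' @param n_sim number of simulated datasets (>= 100).
#' @param seed RNG seed.
#' @param n_group2 samples in the second group (defaults to balanced).
#' @return list of class `power_estimate`: `power`, `mc_se`
#'   (= sqrt(power(1-power)/n_sim)), and the calibration parameters.
#' @export
power_simulation <- function(n_per_group = 5, sd = 10, delta = 30,
                             alpha = 0.005, n_sim = 1000, seed = 1L,
                             n_group2 = n_per_group) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  set.seed(seed)
  n1 <- n_per_group; n2 <- n_group2
  x <- matrix(stats::rnorm(n1 * n_sim, 0, sd), n1)
  y <- matrix(stats::rnorm(n2 * n_sim, delta, sd), n2)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums((x - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((y - rep(m2, each = n2))^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  power <- mean(p < alpha)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_sim),
                 n_per_group = n1, n_group2 = n2, sd = sd, delta = delta,
                 alpha = alpha, n_sim = n_sim, seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power %.3f (MC SE %.4f): n=%dv%d, sd=%g, delta=%g, alpha=%g, %d sims\n",
              x$power, x$mc_se, x$n_per_group, x$n_group2, x$sd, x$delta,
              x$alpha, x$n_sim))
  invisible(x)
}

#' Hierarchical clustering of a locus subset
#'
#' Average-linkage hierarchical clustering on Euclidean distances, over
#' samples (columns; the usual heatmap view of candidate loci) or loci
#' (rows). Loci with missing values are dropped before clustering.
#'
#' @param matrix a `meth_matrix`.
#' @param locus_subset locus ids to cluster on (default: all).
#' @param by `"samples"` or `"loci"`.
#' @return list with `hclust` (the linkage object) and `order` (leaf
#'   labels in dendrogram order).
#' @export
cluster_loci <- function(matrix, locus_subset = NULL,
                         by = c("samples", "loci")) {
  stopifnot(inherits(matrix, "meth_matrix"))
  by <- match.arg(by)
  ids <- if (is.null(locus_subset)) rownames(matrix$scores) else locus_subset
  if (length(ids) == 0) stop("empty locus subset")
  m <- matrix$scores[ids, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (by == "samples") m <- t(m)
  if (nrow(m) < 2) {
    return(list(hclust = NULL, order = rownames(m)))
  }
  hc <- stats::hclust(stats::dist(m), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}
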