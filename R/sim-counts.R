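#' Generate two-enzyme tag counts with ground truth
#'
#' Simulates a HELP-tagging experiment over a locus track. Per-locus
#' sequencing propensities are gamma-distributed (so per-sample MspI counts
#' are negative-binomial across loci); HpaII counts are conditionally
#' Poisson with expectation proportional to the locus's true methylation
#' score on the 0--100 scale (score 100 = unmethylated = full HpaII
#' cutting). True scores follow a bimodal baseline; a configured fraction of
#' loci per exposed group is spiked by `effect_size` score units
#' (hypermethylation = score decrease), including contiguous DMR blocks and
#' a set of loci spiked coherently in every exposed group.
#'
#' The per-locus biological score SD is calibrated down from `score_sd` by
#' the expected counting variance, so the *realized* per-group score SD
#' after scoring matches `score_sd`. Per-sample depth scale factors (the
#' expected total read yield of a fully unmethylated library) are carried in
#' the sample sheet; [compute_scores()] uses them as library-size
#' normalizers.
#'
#' @param config a [sim_config()].
#' @param loci locus track from [generate_loci()].
#' @return list with `counts` (a `locus_counts` object) and `truth` (a
#'   data.table with one row per spiked (locus, group): `locus_id`, `group`,
#'   `true_delta` signed score change, `direction`, `dmr_block`,
#'   `is_differential`).
#' @export
generate_counts <- function(config, loci) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(loci) == 0) stop("empty locus track")
  if (config$frac_differential < 0 || config$frac_differential > 1)
    stop("frac_differential must lie in [0, 1]")
  set.seed(stage_seed(config, "counts"))

  n <- nrow(loci)
  samples <- sim_samples(config)
  ns <- nrow(samples)

  # per-locus sequencing propensity and per-sample library scale
  q <- stats::rgamma(n, shape = config$nb_size, rate = config$nb_size)
  q <- pmax(q, 1e-6)
  p <- q / sum(q)
  nominal <- n * config$mean_depth
  lm_tot <- nominal * stats::runif(ns, config$library_size_range[1],
                                   config$library_size_range[2])
  lh_tot <- nominal * stats::runif(ns, config$library_size_range[1],
                                   config$library_size_range[2])

  # baseline score surface
  mix <- config$baseline_mixture
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  mu0 <- mix$means[comp] + stats::rnorm(n, 0, config$baseline_jitter_sd)
  mu0 <- pmin(pmax(mu0, 2), 98)

  exposed <- setdiff(names(config$groups), config$control_group)
  eff <- config$effect_size
  elig <- list(hyper = mu0 - eff >= 0, hypo = mu0 + eff <= 100)

  delta <- matrix(0, n, length(exposed),
                  dimnames = list(NULL, exposed))
  truth_rows <- list()
  spiked_any <- rep(FALSE, n)

  add_truth <- function(idx, group, d, block = NA_character_) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.table::data.table(
      locus_id = loci$locus_id[idx], group = group, true_delta = d,
      direction = ifelse(d < 0, "hyper", "hypo"), dmr_block = block)
  }

  # loci spiked coherently in every exposed group (direction per locus)
  n_sh <- min(config$n_shared_differential, n)
  if (n_sh > 0 && length(exposed) > 0) {
    n_hyper <- ceiling(n_sh / 2)
    pool_hy <- which(elig$hyper & !spiked_any)
    pool_ho <- which(elig$hypo & !spiked_any)
    sh_hy <- sample(pool_hy, min(n_hyper, length(pool_hy)))
    spiked_any[sh_hy] <- TRUE
    sh_ho <- sample(which(elig$hypo & !spiked_any),
                    min(n_sh - length(sh_hy), length(pool_ho)))
    spiked_any[sh_ho] <- TRUE
    for (g in exposed) {
      delta[sh_hy, g] <- -eff
      delta[sh_ho, g] <- +eff
      add_truth(sh_hy, g, -eff)
      add_truth(sh_ho, g, +eff)
    }
  }

  # contiguous DMR blocks per exposed group
  span <- config$dmr_block_span
  same_chrom_next <- c(loci$chrom[-1] == loci$chrom[-n], FALSE)
  gap_next <- c(loci$start[-1] - loci$end[-n], Inf)
  gap_ok <- same_chrom_next & gap_next <= 10000
  for (g in exposed) {
    dir_g <- config$direction_by_group[[g]]
    for (b in seq_len(config$n_dmr_blocks)) {
      d_b <- if (dir_g == "mixed") {
        if (b %% 2 == 1) "hyper" else "hypo"
      } else dir_g
      ok <- elig[[d_b]] & !spiked_any
      # valid block start: span eligible unspiked loci, all gaps <= 10 kb
      lead_k <- function(x, k) if (k == 0) x else c(x[-seq_len(k)], rep(FALSE, k))
      valid <- rep(TRUE, n)
      for (k in 0:(span - 1)) valid <- valid & lead_k(ok, k)
      for (k in 0:(span - 2)) valid <- valid & lead_k(gap_ok, k)
      starts <- which(valid)
      if (length(starts) == 0) {
        warning("no eligible start for DMR block ", b, " in group ", g)
        next
      }
      st <- if (length(starts) == 1) starts else sample(starts, 1)
      idx <- st:(st + span - 1)
      spiked_any[idx] <- TRUE
      d_val <- if (d_b == "hyper") -eff else eff
      delta[idx, g] <- d_val
      add_truth(idx, g, d_val, block = sprintf("%s_block%02d", g, b))
    }
  }

  # remaining singleton spikes per group
  n_diff <- round(config$frac_differential * n)
  for (g in exposed) {
    have <- sum(delta[, g] != 0)
    need <- max(0, n_diff - have)
    if (need == 0) next
    dir_g <- config$direction_by_group[[g]]
    want <- if (dir_g == "mixed") {
      c(hyper = ceiling(need / 2), hypo = floor(need / 2))
    } else stats::setNames(need, dir_g)
    for (d_b in names(want)) {
      pool <- which(elig[[d_b]] & !spiked_any)
      take <- sample(pool, min(want[[d_b]], length(pool)))
      spiked_any[take] <- TRUE
      d_val <- if (d_b == "hyper") -eff else eff
      delta[take, g] <- d_val
      add_truth(take, g, d_val)
    }
  }

  # true per-sample scores and counts
  mean_lh <- mean(lh_tot)
  d_depth <- mean_lh * p                     # expected unmethylated depth
  hpaii <- matrix(0L, n, ns)
  mspi <- matrix(0L, n, ns)
  colnames(hpaii) <- colnames(mspi) <- samples$sample
  floor_sd <- (0.25 * config$score_sd)^2
  for (s in seq_len(ns)) {
    g <- samples$group[s]
    mu_g <- mu0 + if (g %in% exposed) delta[, g] else 0
    sd_bio <- sqrt(pmax(config$score_sd^2 - 100 * mu_g / d_depth, floor_sd))
    sc <- pmin(pmax(stats::rnorm(n, mu_g, sd_bio), 0), 100)
    hpaii[, s] <- stats::rpois(n, lh_tot[s] * p * sc / 100)
    mspi[, s] <- stats::rpois(n, lm_tot[s] * p)
  }

  if (!is.null(config$zero_inflation_sample)) {
    zs <- config$zero_inflation_sample
    if (!zs %in% samples$sample)
      stop("zero_inflation_sample not among samples: ", zs)
    kill <- sample.int(n, round(config$zero_inflation_frac * n))
    hpaii[kill, zs] <- 0L
  }

  samples[, hpaii_total := lh_tot]
  samples[, mspi_total := lm_tot]

  counts <- structure(list(loci = data.table::copy(loci),
                           samples = samples, hpaii = hpaii, mspi = mspi),
                      class = "locus_counts")
  truth <- if (length(truth_rows)) {
    tr <- data.table::rbindlist(truth_rows)
    tr[, is_differential := TRUE]
    data.table::setorder(tr, locus_id, group)
    tr[]
  } else {
    data.table::data.table(locus_id = character(), group = character(),
                           true_delta = numeric(), direction = character(),
                           dmr_block = character(),
                           is_differential = logical())
  }
  list(counts = counts, truth = truth)
}

#' @export
print.locus_counts <- function(x, ...) {
  cat("HELP-tagging locus count table\n")
  cat("  loci:   ", nrow(x$loci), "\n")
  cat("  samples:", nrow(x$samples), "(",
      paste(unique(x$samples$group), collapse = ", "), ")\n")
  invisible(x)
}
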