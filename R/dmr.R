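#' Call differentially methylated regions (DMRs)
#'
#' A DMR is a maximal run of `min_loci` or more candidate loci that are
#' consecutive in the testable-locus ordering (by default an intervening
#' testable non-candidate locus breaks the run), with the gap between
#' adjacent member loci at most `max_gap` bp and, by default, a uniform
#' direction of change. Defaults implement the standard definition: four or
#' more consecutive differentially methylated loci within 10 kb of each
#' other.
#'
#' @param results differential result table (from [loci_t_test()]), sorted
#'   by (chrom, start) — unsorted input is an error, never silently
#'   re-sorted.
#' @param min_loci minimum run length.
#' @param max_gap maximum distance (bp, end-to-start) between adjacent
#'   member loci.
#' @param break_on_noncandidate if TRUE (default), a testable non-candidate
#'   between two candidates breaks the run; if FALSE only the gap and
#'   direction rules apply.
#' @param require_direction require all members to share hyper/hypo
#'   direction (default TRUE).
#' @return data.table of DMRs: `chrom`, `start`, `end` (0-based half-open
#'   span of member loci), `name`, `n_loci`, `loci` (list column of member
#'   ids), `direction`, `mean_delta`, `min_p`.
#' @export
find_dmrs <- function(results, min_loci = 4, max_gap = 10000,
                      break_on_noncandidate = TRUE,
                      require_direction = TRUE) {
  ord <- order(results$chrom, results$start)
  if (!identical(ord, seq_len(nrow(results))))
    stop("results must be sorted by (chrom, start)")
  tt <- results[testable == TRUE]
  empty <- data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), n_loci = integer(), loci = list(),
    direction = character(), mean_delta = numeric(), min_p = numeric())
  if (nrow(tt) == 0) return(empty)
  tt[, t_idx := seq_len(.N)]
  cand <- tt[candidate == TRUE]
  if (nrow(cand) < min_loci) return(empty)
  n <- nrow(cand)
  new_run <- rep(FALSE, n)
  if (n > 1) {
    prev <- seq_len(n - 1)
    cur <- prev + 1
    brk <- cand$chrom[cur] != cand$chrom[prev] |
      (cand$start[cur] - cand$end[prev]) > max_gap
    if (break_on_noncandidate)
      brk <- brk | cand$t_idx[cur] != cand$t_idx[prev] + 1
    if (require_direction)
      brk <- brk | cand$direction[cur] != cand$direction[prev]
    new_run[cur] <- brk
  }
  cand[, run := cumsum(c(TRUE, new_run[-1]))]
  runs <- cand[, .(chrom = chrom[1], start = start[1], end = end[.N],
                   n_loci = .N, loci = list(locus_id),
                   direction = if (data.table::uniqueN(direction) == 1)
                     direction[1] else "mixed",
                   mean_delta = mean(delta), min_p = min(p)),
               by = run]
  runs <- runs[n_loci >= min_loci]
  if (nrow(runs) == 0) return(empty)
  runs[, name := sprintf("DMR_%s_%d", chrom, seq_len(.N)), by = chrom]
  runs[, run := NULL]
  data.table::setcolorder(runs, c("chrom", "start", "end", "name",
                                  "n_loci", "loci", "direction",
                                  "mean_delta", "min_p"))
  runs[]
}

#' Exhaustive DMR oracle
#'
#' Independent brute-force checker used in tests: enumerates every
#' candidate-index interval, verifies the run conditions element by
#' element, and keeps maximal qualifying runs. Quadratic in the number of
#' candidates — intended for small inputs only.
#'
#' @inheritParams find_dmrs
#' @return same shape as [find_dmrs()] (without names).
#' @export
dmr_oracle <- function(results, min_loci = 4, max_gap = 10000,
                       break_on_noncandidate = TRUE,
                       require_direction = TRUE) {
  ord <- order(results$chrom, results$start)
  if (!identical(ord, seq_len(nrow(results))))
    stop("results must be sorted by (chrom, start)")
  tt <- as.data.frame(results[testable == TRUE])
  ci <- which(tt$candidate)
  valid <- function(i, j) {
    # i..j are positions in the candidate index vector ci
    idx <- ci[i:j]
    for (k in seq_along(idx)[-1]) {
      a <- idx[k - 1]; b <- idx[k]
      if (tt$chrom[a] != tt$chrom[b]) return(FALSE)
      if (tt$start[b] - tt$end[a] > max_gap) return(FALSE)
      if (break_on_noncandidate && b != a + 1) return(FALSE)
      if (require_direction &&
          !identical(tt$direction[a], tt$direction[b])) return(FALSE)
    }
    TRUE
  }
  nc <- length(ci)
  runs <- list()
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      if (valid(i, j)) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(runs) == 0 || nc == 0) {
    return(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      n_loci = integer(), loci = list(), direction = character(),
      mean_delta = numeric(), min_p = numeric()))
  }
  rm <- do.call(rbind, runs)
  maximal <- vapply(seq_len(nrow(rm)), function(r) {
    i <- rm[r, 1]; j <- rm[r, 2]
    !any(rm[, 1] <= i & rm[, 2] >= j & (rm[, 1] < i | rm[, 2] > j))
  }, logical(1))
  rm <- rm[maximal, , drop = FALSE]
  rm <- rm[rm[, 2] - rm[, 1] + 1 >= min_loci, , drop = FALSE]
  if (nrow(rm) == 0) {
    return(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      n_loci = integer(), loci = list(), direction = character(),
      mean_delta = numeric(), min_p = numeric()))
  }
  recs <- lapply(seq_len(nrow(rm)), function(r) {
    idx <- ci[rm[r, 1]:rm[r, 2]]
    data.table::data.table(
      chrom = tt$chrom[idx[1]], start = tt$start[idx[1]],
      end = tt$end[idx[length(idx)]], n_loci = length(idx),
      loci = list(tt$locus_id[idx]),
      direction = if (length(unique(tt$direction[idx])) == 1)
        tt$direction[idx[1]] else "mixed",
      mean_delta = mean(tt$delta[idx]), min_p = min(tt$p[idx]))
  })
  res <- data.table::rbindlist(recs)
  data.table::setorder(res, chrom, start)
  res[]
}
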