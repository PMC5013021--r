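#' Compute per-locus methylation scores
#'
#' Scores each locus/sample on the 0--100 scale: 0 = fully methylated (no
#' HpaII cutting), 100 = unmethylated (HpaII density matches the MspI
#' reference density). The MspI reference is the per-locus pooled MspI
#' count across samples (the assay's methylation-insensitive reference
#' track):
#'
#' score = 100 * min(1, (hpaii / hpaii_total) / (mspi_ref / mspi_ref_total))
#'
#' The per-sample `hpaii_total` normalizer is taken from the sample sheet
#' when present (a depth scale factor on the reference scale, as produced
#' by an upstream scoring pipeline); otherwise the observed HpaII column
#' sum is used. Note the fallback rescales all of a sample's scores by its
#' genome-wide unmethylated fraction — an intrinsic property of any
#' total-normalized digest density — so calibrated factors are preferred
#' whenever available.
#'
#' Loci with zero MspI reference count are unscorable and carry `NA`.
#'
#' @param counts a `locus_counts` object (see [generate_counts()] /
#'   [read_counts_tsv()]).
#' @return a `meth_matrix`: list with `scores` (loci x samples matrix,
#'   rownames = locus ids), `loci`, `samples`.
#' @export
compute_scores <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  hp <- counts$hpaii
  totals <- if (!is.null(counts$samples$hpaii_total)) {
    counts$samples$hpaii_total
  } else {
    colSums(hp)
  }
  if (any(totals <= 0)) stop("all-zero or non-positive library total")
  ref <- rowSums(counts$mspi)
  ref_total <- sum(ref)
  if (ref_total <= 0) stop("MspI reference is empty")
  dens_ref <- ref / ref_total
  dens_h <- sweep(hp, 2, totals, "/")
  sc <- dens_h / dens_ref
  sc[sc > 1] <- 1          # HpaII density can stochastically exceed the
  sc <- 100 * sc           # reference; the scale is bounded at 100
  sc[ref == 0, ] <- NA_real_
  rownames(sc) <- counts$loci$locus_id
  structure(list(scores = sc, loci = data.table::copy(counts$loci),
                 samples = counts$samples[, .(sample, group)]),
            class = "meth_matrix")
}

#' Per-locus, per-sample confidence scores
#'
#' Confidence reflects how reliably a locus is measured in a sample: the
#' depth-normalized MspI reference density at the locus, scaled by the mean
#' per-sample depth, damped toward zero when the sample's local coverage
#' (HpaII + MspI reads at the locus) is low:
#'
#' conf = (mspi_ref / mspi_ref_total) * mean_depth * (1 - exp(-(hpaii + mspi)))
#'
#' It is monotone non-decreasing in both enzymes' counts.
#'
#' @param counts a `locus_counts` object.
#' @return numeric matrix (loci x samples), rownames = locus ids.
#' @export
compute_confidence <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  ref <- rowSums(counts$mspi)
  ref_total <- sum(ref)
  if (ref_total <= 0) stop("MspI reference is empty")
  totals <- if (!is.null(counts$samples$hpaii_total)) {
    counts$samples$hpaii_total
  } else colSums(counts$hpaii)
  s_bar <- mean(totals)
  conf <- (ref / ref_total) * s_bar *
    (1 - exp(-(counts$hpaii + counts$mspi)))
  rownames(conf) <- counts$loci$locus_id
  conf
}

#' Filter loci by confidence
#'
#' A locus is dropped when any considered sample's confidence falls below
#' the expected mean confidence, and unscorable loci (all-`NA` scores) are
#' dropped. Two readings of "expected mean" are available:
#'
#' * `"global"` (default): `factor` times the mean confidence over the
#'   whole assay (all loci of the confidence matrix, considered samples).
#'   This removes systematically under-covered loci and reproduces the
#'   heavy locus attrition seen in real two-enzyme data, where roughly
#'   half the assayed loci are not reliably measurable. Because the
#'   threshold is computed from the full confidence matrix, the filter is
#'   idempotent.
#' * `"per_locus"`: `factor` times the locus's own across-sample mean
#'   confidence — an adaptive rule that only catches loci where one sample
#'   is much weaker than that locus's typical coverage.
#'
#' @param matrix a `meth_matrix`.
#' @param confidence matrix from [compute_confidence()] (full assay; used
#'   for the global threshold even when `matrix` holds a locus subset).
#' @param samples optional character vector restricting the rule to a
#'   sample subset, e.g. the two groups of one comparison.
#' @param factor multiple of the expected mean confidence below which a
#'   sample fails the locus; defaults to 1 for the global rule and 0.5
#'   for the per-locus rule (a sample at half its locus's typical
#'   confidence).
#' @param mode `"global"` or `"per_locus"`.
#' @return filtered `meth_matrix` (all samples retained, loci subset), with
#'   a `filter_report` attribute (input/retained/dropped counts).
#' @export
filter_loci <- function(matrix, confidence, samples = NULL, factor = NULL,
                        mode = c("global", "per_locus")) {
  stopifnot(inherits(matrix, "meth_matrix"))
  mode <- match.arg(mode)
  if (is.null(factor)) factor <- if (mode == "global") 1 else 0.5
  keep_s <- if (is.null(samples)) matrix$samples$sample else samples
  miss <- setdiff(keep_s, colnames(confidence))
  if (length(miss)) stop("samples missing from confidence: ",
                         paste(miss, collapse = ", "))
  conf <- confidence[matrix$loci$locus_id, keep_s, drop = FALSE]
  expected <- if (mode == "global") {
    mean(confidence[, keep_s])
  } else {
    rowMeans(conf)
  }
  low <- rowSums(conf < factor * expected) > 0
  unscorable <- rowSums(!is.na(matrix$scores[, keep_s, drop = FALSE])) == 0
  keep <- !low & !unscorable
  if (!any(keep))
    stop("no loci survive confidence filtering (empty result)")
  out <- structure(list(scores = matrix$scores[keep, , drop = FALSE],
                        loci = matrix$loci[keep],
                        samples = matrix$samples),
                   class = "meth_matrix")
  attr(out, "filter_report") <- list(
    n_input = nrow(matrix$loci), n_retained = sum(keep),
    n_dropped_confidence = sum(low & !unscorable),
    n_unscorable = sum(unscorable), factor = factor, mode = mode,
    samples = keep_s)
  out
}

#' Flag aberrant samples by zero-score overrepresentation
#'
#' A sample is flagged when its fraction of zero-score loci exceeds the
#' across-sample median by more than `n_mad` robust MADs — the failure mode
#' of a degraded HpaII library, where cutting drops out and scores pile up
#' at 0.
#'
#' @param matrix a `meth_matrix`.
#' @param n_mad flagging threshold in MAD units.
#' @return data.table with `sample`, `group`, `zero_frac`, `flagged`.
#' @export
sample_qc <- function(matrix, n_mad = 3) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (nrow(matrix$samples) < 3) {
    warning("fewer than 3 samples; QC skipped")
    return(data.table::data.table(sample = matrix$samples$sample,
                                  group = matrix$samples$group,
                                  zero_frac = NA_real_, flagged = FALSE))
  }
  zf <- colMeans(matrix$scores == 0, na.rm = TRUE)
  thr <- stats::median(zf) + n_mad * stats::mad(zf)
  data.table::data.table(sample = matrix$samples$sample,
                         group = matrix$samples$group,
                         zero_frac = as.numeric(zf),
                         flagged = as.numeric(zf) > thr)
}

#' Drop samples from a methylation matrix
#'
#' @param matrix a `meth_matrix`.
#' @param drop character vector of sample names to remove.
#' @return `meth_matrix` without those samples.
#' @export
drop_samples <- function(matrix, drop) {
  stopifnot(inherits(matrix, "meth_matrix"))
  keep <- setdiff(matrix$samples$sample, drop)
  structure(list(scores = matrix$scores[, keep, drop = FALSE],
                 loci = matrix$loci,
                 samples = matrix$samples[sample %in% keep]),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("Methylation score matrix:", nrow(x$scores), "loci x",
      ncol(x$scores), "samples\n")
  invisible(x)
}
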