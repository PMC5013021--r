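# Shared fixture builders. Everything is generated in code; no data files.

# small simulation (~5k loci on one chromosome) used across module tests
small_config <- function(seed = 7, ...) {
  sim_config(n_chromosomes = 1, chromosome_length = 1e7,
             n_genes = 200, n_gene_sets = 8, seed = seed, ...)
}

# hand-built methylation matrix from a score matrix and group labels
make_matrix <- function(scores, groups, spacing = 2000) {
  n <- nrow(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("L%05d", seq_len(n))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0(groups, stats::ave(seq_along(groups),
                                                  groups, FUN = seq_along))
  start <- seq(0, by = spacing, length.out = n)
  structure(list(
    scores = scores,
    loci = data.table::data.table(locus_id = rownames(scores),
                                  chrom = "chr1", start = start,
                                  end = start + 2),
    samples = data.table::data.table(sample = colnames(scores),
                                     group = groups)),
    class = "meth_matrix")
}

# hand-built two-enzyme count table (single-locus scale fixtures)
make_counts <- function(hpaii, mspi, hpaii_total = NULL,
                        mspi_total = NULL, groups = NULL,
                        start = seq(0, by = 2000,
                                    length.out = nrow(hpaii))) {
  n <- nrow(hpaii); ns <- ncol(hpaii)
  sam <- if (is.null(colnames(hpaii))) paste0("s", seq_len(ns))
         else colnames(hpaii)
  colnames(hpaii) <- colnames(mspi) <- sam
  samples <- data.table::data.table(
    sample = sam,
    group = if (is.null(groups)) rep("g", ns) else groups)
  ht <- hpaii_total; mt <- mspi_total
  if (!is.null(ht)) samples[, hpaii_total := ht]
  if (!is.null(mt)) samples[, mspi_total := mt]
  structure(list(
    loci = data.table::data.table(locus_id = sprintf("L%05d", seq_len(n)),
                                  chrom = "chr1", start = start,
                                  end = start + 2),
    samples = samples, hpaii = hpaii, mspi = mspi),
    class = "locus_counts")
}

# random differential-result fixture for DMR equivalence testing
random_results_fixture <- function(seed, max_loci = 120,
                                   cand_rate = 0.35) {
  set.seed(seed)
  nl <- sample(10:max_loci, 1)
  st <- cumsum(sample(c(500, 2000, 6000, 12000), nl, replace = TRUE,
                      prob = c(0.3, 0.4, 0.2, 0.1)))
  f <- data.table::data.table(
    locus_id = sprintf("x%04d", seq_len(nl)),
    chrom = sample(c("chr1", "chr2"), 1),
    start = st, end = st + 2,
    delta = stats::rnorm(nl, 0, 40), t = 0, df = 9,
    p = stats::runif(nl)^2,
    testable = stats::runif(nl) > 0.1)
  f[, candidate := testable & abs(delta) > 30 & p < cand_rate]
  f[, direction := data.table::fifelse(delta < 0, "hyper", "hypo")]
  f[]
}

dmr_tables_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  identical(unlist(a$loci), unlist(b$loci)) &&
    all(a$chrom == b$chrom) && all(a$start == b$start) &&
    all(a$end == b$end) && all(a$direction == b$direction)
}
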