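#' HpaII-site-count bias weights for gene sampling
#'
#' Genes with more assayed HpaII loci are more likely to contain a
#' candidate locus by chance alone. To remove that bias from set
#' enrichment, genes are binned by site-count quantiles and each gene's
#' sampling weight is the empirical probability of being differentially
#' methylated in its bin, floored by a half-count pseudo-rate so no bin has
#' weight zero; weights are normalized to sum to 1 over the universe.
#'
#' @param site_counts named numeric vector: gene id -> number of HpaII
#'   sites (>= 0); the names define the universe.
#' @param dm_genes character vector of differentially methylated gene ids.
#' @param n_bins number of quantile bins.
#' @return named weight vector over the universe, summing to 1.
#' @export
compute_bias_weights <- function(site_counts, dm_genes, n_bins = 10) {
  if (is.null(names(site_counts))) stop("site_counts must be named by gene")
  if (any(site_counts < 0)) stop("negative site counts")
  universe <- names(site_counts)
  dm <- intersect(dm_genes, universe)
  if (length(dm) < 1) stop("need at least one DM gene in the universe")
  br <- unique(stats::quantile(site_counts, probs = seq(0, 1,
                                                        length.out = n_bins + 1)))
  if (length(br) < 3) {
    warning("no site-count variation across genes; using uniform weights")
    w <- rep(1 / length(universe), length(universe))
    names(w) <- universe
    return(w)
  }
  bin <- cut(site_counts, breaks = br, include.lowest = TRUE)
  is_dm <- universe %in% dm
  n_b <- tapply(rep(1, length(bin)), bin, sum, default = 0)
  dm_b <- tapply(as.numeric(is_dm), bin, sum, default = 0)
  rate <- pmax(dm_b, 0.5) / pmax(n_b, 1)
  w <- rate[as.integer(bin)]
  w <- as.numeric(w) / sum(w)
  names(w) <- universe
  w
}

# shared weighted draws: m genes per draw, without replacement
sample_dm_draws <- function(weights, m, n_samples) {
  N <- length(weights)
  if (m > N) stop("more DM genes than universe genes")
  vapply(seq_len(n_samples),
         function(i) sample.int(N, m, replace = FALSE, prob = weights),
         integer(m))
}

#' Weighted random-sampling set enrichment
#'
#' Draws `n_samples` gene sets of size |dm_genes| from the universe without
#' replacement, with probability proportional to the bias weights, and
#' compares the observed overlap between `gene_set` and the differentially
#' methylated genes against the sampled overlap distribution. Add-one
#' estimators avoid zero p-values:
#' p_over = (1 + #\{overlap >= observed\}) / (n_samples + 1), p_under
#' analogous with <=. With uniform weights this converges to the
#' hypergeometric tail.
#'
#' @param gene_set character vector of member gene ids.
#' @param dm_genes differentially methylated gene ids.
#' @param weights named weight vector over the universe (see
#'   [compute_bias_weights()]).
#' @param n_samples number of random draws (>= 1000).
#' @param seed RNG seed.
#' @param draws optional precomputed index matrix from an enclosing
#'   [enrich_all()] call (shared across sets).
#' @return one-row data.table: `set_name` (NA here), `n_set`,
#'   `n_dm_in_set`, `p_over`, `p_under`, `n_samples`, `seed`.
#' @export
weighted_enrichment <- function(gene_set, dm_genes, weights,
                                n_samples = 10000, seed = 1L,
                                draws = NULL) {
  if (n_samples < 1000) stop("n_samples must be >= 1000")
  universe <- names(weights)
  set_u <- intersect(gene_set, universe)
  dm <- intersect(dm_genes, universe)
  m <- length(dm)
  if (m > length(universe)) stop("more DM genes than universe genes")
  k_obs <- length(intersect(set_u, dm))
  if (is.null(draws)) {
    set.seed(seed)
    draws <- sample_dm_draws(weights, m, n_samples)
  }
  member <- universe %in% set_u
  ov <- colSums(matrix(member[draws], nrow = m))
  data.table::data.table(
    set_name = NA_character_, n_set = length(set_u), n_dm_in_set = k_obs,
    p_over = (1 + sum(ov >= k_obs)) / (n_samples + 1),
    p_under = (1 + sum(ov <= k_obs)) / (n_samples + 1),
    n_samples = n_samples, seed = seed)
}

#' Enrichment over a gene-set collection
#'
#' Runs [weighted_enrichment()] for every set, sharing one matrix of
#' weighted draws across sets for efficiency (p-values are exchangeable
#' with independent runs up to Monte-Carlo error). Sets with no member in
#' the universe are dropped with a message.
#'
#' @param collection named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @inheritParams weighted_enrichment
#' @return data.table, one row per set, sorted by `p_over`.
#' @export
enrich_all <- function(collection, dm_genes, weights, n_samples = 10000,
                       seed = 1L) {
  universe <- names(weights)
  dm <- intersect(dm_genes, universe)
  keep <- vapply(collection, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  if (any(!keep))
    message("dropping ", sum(!keep), " empty gene set(s): ",
            paste(names(collection)[!keep], collapse = ", "))
  collection <- collection[keep]
  set.seed(seed)
  draws <- sample_dm_draws(weights, length(dm), n_samples)
  res <- data.table::rbindlist(lapply(names(collection), function(nm) {
    r <- weighted_enrichment(collection[[nm]], dm, weights,
                             n_samples = n_samples, seed = seed,
                             draws = draws)
    r[, set_name := nm]
    r
  }))
  data.table::setorder(res, p_over)
  res[]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
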