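#' Generate synthetic gene models with HpaII-site counts
#'
#' Gene spans are log-normally distributed so per-gene HpaII-site counts
#' span more than an order of magnitude — the site-count bias the
#' enrichment stage corrects for. The per-gene site count equals the number
#' of loci overlapping the gene's mapping window (10 kb upstream of the TSS
#' through 10 kb downstream of the gene body), recomputable with
#' [build_windows()] + [map_loci()].
#'
#' @param config a [sim_config()].
#' @param loci locus track from [generate_loci()].
#' @return data.table with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`, `tes`, `n_hpaii_sites`.
#' @export
generate_annotation <- function(config, loci) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(loci) == 0) stop("empty locus track")
  set.seed(stage_seed(config, "annotation"))
  ng <- config$n_genes
  chrom <- paste0("chr", sample.int(config$n_chromosomes, ng, replace = TRUE))
  len <- round(stats::rlnorm(ng, meanlog = log(2e4), sdlog = 1.2))
  len <- pmin(pmax(len, 500), round(config$chromosome_length / 50))
  start <- floor(stats::runif(ng) * (config$chromosome_length - len))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  genes <- data.table::data.table(
    gene_id = sprintf("G%05d", seq_len(ng)),
    chrom = chrom, start = start, end = start + len, strand = strand)
  genes[, tss := ifelse(strand == "+", start, end)]
  genes[, tes := ifelse(strand == "+", end, start)]
  data.table::setorder(genes, chrom, start)

  win <- build_windows(genes, upstream = 10000, downstream = 10000)
  wgr <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$window_start + 1, win$window_end))
  lgr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start + 1, loci$end))
  hits <- GenomicRanges::countOverlaps(wgr, lgr)
  genes[, n_hpaii_sites := hits]
  genes[]
}

#' Generate synthetic gene sets
#'
#' Draws gene sets of varying size uniformly from the gene universe, for
#' exercising the bias-corrected enrichment stage.
#'
#' @param config a [sim_config()].
#' @param genes gene table from [generate_annotation()].
#' @return named list of character vectors (set name -> gene ids).
#' @export
generate_gene_sets <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "gene_sets"))
  ng <- nrow(genes)
  max_size <- max(10L, min(200L, floor(ng / 2)))
  sets <- lapply(seq_len(config$n_gene_sets), function(i) {
    size <- sample(10:max_size, 1)
    sample(genes$gene_id, min(size, ng))
  })
  names(sets) <- sprintf("set%03d", seq_len(config$n_gene_sets))
  sets
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a relative-expression experiment: per animal, target-gene Ct is
#' baseline − log2(fold for the animal's group) plus an animal-level
#' loading offset (shared with the reference gene, so it cancels in dCt)
#' and replicate-level noise; the reference gene's fold is fixed at 1.
#'
#' @param config a [sim_config()]; see the `expression` element.
#' @return data.table with `animal_id`, `group`, `gene`, `replicate`, `ct`.
#' @export
generate_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  if (length(config$groups) < 2) stop("need at least 2 groups")
  set.seed(stage_seed(config, "ct"))
  groups <- names(config$groups)
  targets <- names(ex$target_folds)
  base_ct <- stats::setNames(24 + seq_along(targets), targets)
  ref_base <- 18
  rows <- list()
  for (g in groups) {
    for (a in seq_len(ex$n_animals)) {
      animal <- sprintf("%s_a%d", g, a)
      offset <- stats::rnorm(1, 0, 0.2)         # plate/loading effect
      for (gene in c(targets, ex$ref_gene)) {
        if (gene == ex$ref_gene) {
          mu <- ref_base + offset
        } else {
          fold <- ex$target_folds[[gene]]
          f <- if (g %in% names(fold)) fold[[g]] else 1
          mu <- base_ct[[gene]] - log2(f) + offset + stats::rnorm(1, 0, 0.1)
        }
        ct <- mu + stats::rnorm(ex$n_replicates, 0, ex$ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          animal_id = animal, group = g, gene = gene,
          replicate = seq_len(ex$n_replicates), ct = ct)
      }
    }
  }
  data.table::rbindlist(rows)
}
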