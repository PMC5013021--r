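#' Build gene mapping windows
#'
#' The default ("results") window runs from `upstream` bp upstream of the
#' transcription start site to `downstream` bp downstream of the gene body
#' end, in transcription orientation; the "methods" variant stops at the
#' transcription end site (downstream = 0). Windows are 0-based half-open
#' and clipped at position 0.
#'
#' @param genes data.table with `gene_id`, `chrom`, `strand`, `tss`, `tes`
#'   (bp; tss upstream of tes in transcription orientation).
#' @param upstream,downstream window extensions in bp.
#' @param mode `"results"` (default) or `"methods"` (no downstream
#'   extension).
#' @return copy of `genes` with `window_start`, `window_end`.
#' @export
build_windows <- function(genes, upstream = 10000, downstream = 10000,
                          mode = c("results", "methods")) {
  mode <- match.arg(mode)
  if (mode == "methods") downstream <- 0
  g <- data.table::as.data.table(genes)
  bad <- (g$strand == "+" & g$tss >= g$tes) |
    (g$strand == "-" & g$tss <= g$tes)
  if (any(bad))
    stop("tss/tes inverted for strand in genes: ",
         paste(utils::head(g$gene_id[bad], 5), collapse = ", "))
  g[, window_start := pmax(0, data.table::fifelse(
    strand == "+", tss - upstream, tes - downstream))]
  g[, window_end := data.table::fifelse(
    strand == "+", tes + downstream, tss + upstream)]
  g[]
}

#' Map loci to gene windows
#'
#' Associates every locus with every gene whose mapping window overlaps it
#' (0-based half-open overlap; a locus starting exactly at `window_end` is
#' not mapped). Many-to-many: one locus may hit several genes. The
#' `relation` column classifies the hit as `upstream`, `body` or
#' `downstream` relative to the gene body in transcription orientation.
#'
#' @param loci data.table with `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted.
#' @param windowed_genes output of [build_windows()], sorted.
#' @return association data.table: `locus_id`, `gene_id`, `relation`.
#' @export
map_loci <- function(loci, windowed_genes) {
  g <- windowed_genes
  missing_chroms <- setdiff(unique(loci$chrom), unique(g$chrom))
  if (length(missing_chroms))
    stop("chromosome names absent from gene track: ",
         paste(missing_chroms, collapse = ", "))
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1, loci$end))
  wgr <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(g$window_start + 1,
                                                 g$window_end))
  hits <- GenomicRanges::findOverlaps(lgr, wgr)
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  body_start <- pmin(g$tss, g$tes)[gi]
  body_end <- pmax(g$tss, g$tes)[gi]
  mid <- (loci$start[li] + loci$end[li]) / 2
  before <- mid < body_start
  after <- mid >= body_end
  plus <- g$strand[gi] == "+"
  relation <- rep("body", length(li))
  relation[before & plus] <- "upstream"
  relation[before & !plus] <- "downstream"
  relation[after & plus] <- "downstream"
  relation[after & !plus] <- "upstream"
  data.table::data.table(locus_id = loci$locus_id[li],
                         gene_id = g$gene_id[gi],
                         relation = relation)
}

#' Map DMRs to gene windows via member loci
#'
#' A DMR maps to a gene iff at least one member locus maps.
#'
#' @param dmrs table from [find_dmrs()].
#' @param windowed_genes output of [build_windows()].
#' @param loci locus coordinate table covering the member ids.
#' @return data.table: `name` (DMR), `gene_id`.
#' @export
map_dmrs <- function(dmrs, windowed_genes, loci) {
  if (nrow(dmrs) == 0)
    return(data.table::data.table(name = character(), gene_id = character()))
  member <- data.table::data.table(
    name = rep(dmrs$name, lengths(dmrs$loci)),
    locus_id = unlist(dmrs$loci))
  sub <- loci[locus_id %in% member$locus_id]
  assoc <- map_loci(sub, windowed_genes)
  out <- unique(merge(member, assoc, by = "locus_id",
                      allow.cartesian = TRUE)[, .(name, gene_id)])
  data.table::setorder(out, name, gene_id)
  out[]
}

#' Per-gene differential-methylation summary
#'
#' @param associations table from [map_loci()].
#' @param dm_locus_ids ids of candidate (differentially methylated) loci.
#' @return data.table per gene: `gene_id`, `n_loci` mapped,
#'   `n_candidate_loci`, `differentially_methylated` (>= 1 mapped
#'   candidate).
#' @export
gene_dm_summary <- function(associations, dm_locus_ids) {
  s <- associations[, .(n_loci = .N,
                        n_candidate_loci = sum(locus_id %in% dm_locus_ids)),
                    by = gene_id]
  s[, differentially_methylated := n_candidate_loci > 0]
  s[]
}
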