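#' Write / read a locus count table
#'
#' Tab-delimited flat form: `locus_id`, `chrom`, `start`, `end`, then one
#' `<sample>.hpaii` and `<sample>.mspi` column per sample. The sample sheet
#' (sample, group, depth scale factors) travels in a companion
#' `<path>.samples.tsv`.
#'
#' @param counts a `locus_counts` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "locus_counts"))
  hp <- data.table::as.data.table(counts$hpaii)
  data.table::setnames(hp, paste0(names(hp), ".hpaii"))
  ms <- data.table::as.data.table(counts$mspi)
  data.table::setnames(ms, paste0(names(ms), ".mspi"))
  flat <- cbind(counts$loci, hp, ms)
  data.table::fwrite(flat, path, sep = "\t")
  data.table::fwrite(counts$samples, paste0(path, ".samples.tsv"),
                     sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  flat <- data.table::fread(path, sep = "\t")
  samples <- data.table::fread(paste0(path, ".samples.tsv"), sep = "\t")
  loci <- flat[, .(locus_id, chrom, start, end)]
  hp_cols <- paste0(samples$sample, ".hpaii")
  ms_cols <- paste0(samples$sample, ".mspi")
  hpaii <- as.matrix(flat[, ..hp_cols])
  mspi <- as.matrix(flat[, ..ms_cols])
  colnames(hpaii) <- colnames(mspi) <- samples$sample
  structure(list(loci = loci, samples = samples, hpaii = hpaii,
                 mspi = mspi), class = "locus_counts")
}

#' Write a methylation score matrix as TSV
#'
#' Locus rows, sample columns; group labels in a companion samples file.
#'
#' @param matrix a `meth_matrix`.
#' @param path output TSV path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "meth_matrix"))
  dt <- cbind(matrix$loci, data.table::as.data.table(matrix$scores))
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(matrix$samples, paste0(path, ".samples.tsv"),
                     sep = "\t")
  invisible(path)
}

#' Export a locus track as BED4
#'
#' 0-based half-open, name = locus id (via rtracklayer).
#'
#' @param loci locus data.table.
#' @param path output .bed path.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1, loci$end))
  names(gr) <- loci$locus_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Export gene models as GTF
#'
#' One `gene` feature per gene (1-based inclusive coordinates, as GTF
#' requires), via rtracklayer.
#'
#' @param genes gene table from [generate_annotation()].
#' @param path output .gtf path.
#' @export
write_genes_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$source <- "helptagdm"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `gene` features (or all features if none are typed `gene`) and
#' converts to the package's 0-based gene table with tss/tes by strand.
#'
#' @param path .gtf path.
#' @return gene data.table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`).
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  g <- data.table::data.table(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  g[strand == "*", strand := "+"]
  g[, tss := ifelse(strand == "+", start, end)]
  g[, tes := ifelse(strand == "+", end, start)]
  data.table::setorder(g, chrom, start)
  g[]
}

#' Write DMRs as BED6+3
#'
#' chrom, start, end, name, score = -log10(min p) capped at 99, strand '.',
#' then n_loci, mean_delta, direction.
#'
#' @param dmrs table from [find_dmrs()].
#' @param path output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  bed <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$name, score = pmin(99, -log10(pmax(dmrs$min_p, 1e-99))),
    strand = ".", n_loci = dmrs$n_loci, mean_delta = dmrs$mean_delta,
    direction = dmrs$direction)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
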