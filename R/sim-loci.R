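#' Generate a genomic track of HpaII loci
#'
#' Places loci along each chromosome with exponentially distributed
#' inter-locus gaps (mean = `mean_locus_spacing`), mimicking the spacing of
#' HpaII (CCGG) sites in a mammalian genome. Coordinates are 0-based
#' half-open; each locus is a 2-bp CpG-site anchor.
#'
#' @param config a [sim_config()].
#' @return data.table with `locus_id`, `chrom`, `start`, `end`, sorted by
#'   (chrom, start).
#' @export
generate_loci <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chromosome_length <= config$mean_locus_spacing)
    stop("chromosome too short for the requested locus spacing")
  set.seed(stage_seed(config, "loci"))
  per_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
    # draw ~20% more gaps than the expected count, then truncate
    n_exp <- ceiling(config$chromosome_length / config$mean_locus_spacing)
    gaps <- stats::rexp(ceiling(n_exp * 1.2) + 10, 1 / config$mean_locus_spacing)
    pos <- floor(cumsum(gaps))
    pos <- pos[pos < config$chromosome_length - 1]
    if (length(pos) == 0)
      stop("chromosome too short for the requested locus spacing")
    data.table::data.table(chrom = paste0("chr", ci),
                           start = pos, end = pos + 2)
  })
  loci <- data.table::rbindlist(per_chrom)
  loci <- unique(loci, by = c("chrom", "start"))
  data.table::setorder(loci, chrom, start)
  if (!is.null(config$n_loci)) {
    if (nrow(loci) < config$n_loci)
      stop("chromosomes too short for the requested locus count (",
           nrow(loci), " < ", config$n_loci, ")")
    loci <- loci[seq_len(config$n_loci)]
  }
  loci[, locus_id := sprintf("L%07d", seq_len(.N))]
  data.table::setcolorder(loci, c("locus_id", "chrom", "start", "end"))
  loci[]
}
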