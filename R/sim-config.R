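#' Simulation configuration
#'
#' Builds the configuration object consumed by every `generate_*()` function.
#' Defaults emulate the study design the pipeline targets: four groups
#' (young control `Con` n=5, maternal undernutrition `UN` n=6, maternal
#' overnutrition `ON` n=5, aged `Old` n=6), HpaII loci spaced on average
#' 2,000 bp apart, methylation scores on the 0--100 scale (0 = fully
#' methylated, 100 = unmethylated) with per-group standard deviation of
#' about 10 score units, and spiked differential loci of 30 score units:
#' `UN` spikes are hypermethylating (score decrease), `Old` spikes
#' hypomethylating (score increase), `ON` spikes mixed with no net shift.
#'
#' @param n_chromosomes number of simulated chromosomes.
#' @param chromosome_length length of each chromosome in bp.
#' @param mean_locus_spacing mean distance between adjacent HpaII loci (bp).
#' @param n_loci optional cap on the total number of loci; `NULL` lets the
#'   count follow from spacing and chromosome length. An error is raised if
#'   the chromosomes cannot hold the requested count.
#' @param groups named integer vector: group name -> number of samples.
#' @param baseline_mixture list with `weights` and `means` of the bimodal
#'   baseline score distribution on \[0,100\].
#' @param baseline_jitter_sd SD of per-locus jitter around the component
#'   means (score units).
#' @param score_sd target per-group SD of realized scores (score units).
#' @param frac_differential fraction of loci spiked per exposed group.
#' @param effect_size absolute spiked group-mean difference (score units).
#' @param direction_by_group named character vector mapping each non-control
#'   group to `"hyper"` (score decrease), `"hypo"` (score increase) or
#'   `"mixed"`.
#' @param control_group name of the reference group.
#' @param n_shared_differential number of loci spiked (coherent direction)
#'   in every exposed group, emulating exposure/aging-shared loci.
#' @param n_dmr_blocks number of spiked contiguous DMR blocks per exposed
#'   group.
#' @param dmr_block_span loci per spiked DMR block (>= 4).
#' @param mean_depth mean MspI read depth per locus per sample.
#' @param nb_size gamma/negative-binomial dispersion of per-locus depth
#'   (smaller = more overdispersed).
#' @param library_size_range multiplicative range of per-sample library
#'   sizes around the nominal total.
#' @param zero_inflation_sample optional sample name whose HpaII counts are
#'   partially zeroed to emulate a failed library.
#' @param zero_inflation_frac fraction of loci zeroed in that sample.
#' @param n_genes number of simulated gene models.
#' @param n_gene_sets number of gene sets written to GMT.
#' @param expression list describing the qPCR stage: `target_folds` (named
#'   list gene -> named fold-change vector per group), `ref_gene`,
#'   `n_animals`, `n_replicates`, `ct_noise_sd` (cycles).
#' @param seed integer seed; all generators are deterministic given
#'   (config, seed).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       chromosome_length = 5e7,
                       mean_locus_spacing = 2000,
                       n_loci = NULL,
                       groups = c(Con = 5L, UN = 6L, ON = 5L, Old = 6L),
                       baseline_mixture = list(weights = c(0.45, 0.55),
                                               means = c(15, 85)),
                       baseline_jitter_sd = 5,
                       score_sd = 10,
                       frac_differential = 0.01,
                       effect_size = 30,
                       direction_by_group = c(UN = "hyper", ON = "mixed",
                                              Old = "hypo"),
                       control_group = "Con",
                       n_shared_differential = 24,
                       n_dmr_blocks = 5,
                       dmr_block_span = 6,
                       mean_depth = 300,
                       nb_size = 1.5,
                       library_size_range = c(0.8, 1.2),
                       zero_inflation_sample = NULL,
                       zero_inflation_frac = 0.4,
                       n_genes = 2000,
                       n_gene_sets = 30,
                       expression = list(
                         target_folds = list(
                           Ncor2 = c(Con = 1, UN = 10, ON = 4, Old = 6),
                           Smad3 = c(Con = 1, UN = 0.5, ON = 0.6, Old = 0.5)
                         ),
                         ref_gene = "Rps3",
                         n_animals = 6L,
                         n_replicates = 3L,
                         ct_noise_sd = 0.15
                       ),
                       seed = 1L) {
  if (mean_locus_spacing <= 0 || chromosome_length <= 0)
    stop("spacing and chromosome length must be positive")
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must lie in [0, 1]")
  if (dmr_block_span < 4)
    stop("dmr_block_span must be >= 4 (the minimum DMR run length)")
  if (any(groups < 2))
    stop("every group needs at least 2 samples")
  if (!control_group %in% names(groups))
    stop("control_group not among groups")
  stopifnot(length(baseline_mixture$weights) == length(baseline_mixture$means))
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    mean_locus_spacing = mean_locus_spacing,
    n_loci = if (!is.null(n_loci)) as.integer(n_loci),
    groups = groups,
    baseline_mixture = baseline_mixture,
    baseline_jitter_sd = baseline_jitter_sd,
    score_sd = score_sd,
    frac_differential = frac_differential,
    effect_size = effect_size,
    direction_by_group = direction_by_group,
    control_group = control_group,
    n_shared_differential = n_shared_differential,
    n_dmr_blocks = n_dmr_blocks,
    dmr_block_span = dmr_block_span,
    mean_depth = mean_depth,
    nb_size = nb_size,
    library_size_range = library_size_range,
    zero_inflation_sample = zero_inflation_sample,
    zero_inflation_frac = zero_inflation_frac,
    n_genes = as.integer(n_genes),
    n_gene_sets = as.integer(n_gene_sets),
    expression = expression,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Sample sheet implied by a simulation config
#'
#' @param config a `sim_config`.
#' @return data.table with columns `sample` and `group`.
#' @export
sim_samples <- function(config) {
  grp <- rep(names(config$groups), config$groups)
  idx <- unlist(lapply(config$groups, seq_len), use.names = FALSE)
  data.table::data.table(sample = paste0(grp, idx), group = grp)
}

# Deterministic per-stage sub-seed so generators can be called in any order.
# Kept below 2^31 - 1.
stage_seed <- function(config, stage) {
  offs <- c(loci = 11L, counts = 23L, annotation = 37L, gene_sets = 41L,
            ct = 53L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (config$seed %% 100000L) * 1000L + offs[[stage]]
}
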