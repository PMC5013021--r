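# tiny polynomial rolling hash over a serialized object, for manifest
# config fingerprints (not cryptographic)
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pairwise and full overlap of candidate sets
#'
#' Exact set intersections by id (locus or gene), for the
#' shared-across-comparisons summaries.
#'
#' @param candidate_sets named list of >= 2 character vectors.
#' @return list: `sizes`, `pairwise` (data.table `set_a`, `set_b`, `n`),
#'   `all_n` (size of the full intersection).
#' @export
overlap_summary <- function(candidate_sets) {
  if (length(candidate_sets) < 2) stop("need at least 2 sets")
  sets <- lapply(candidate_sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  pw <- data.table::data.table(
    set_a = pairs[1, ], set_b = pairs[2, ],
    n = apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))))
  list(sizes = vapply(sets, length, integer(1)),
       pairwise = pw,
       all_n = length(Reduce(intersect, sets)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> score -> QC -> per-comparison differential
#' testing (control vs each exposed group) -> direction enrichment ->
#' optional permutation correction -> DMR calling -> gene mapping ->
#' overlap summaries -> optional bias-corrected set enrichment -> optional
#' qPCR expression stage, and assembles a run manifest (config hash, seeds,
#' per-stage counts) sufficient to re-run bit-identically.
#'
#' @param config a [sim_config()] (or a YAML path readable by
#'   [read_pipeline_config()]).
#' @param outdir optional directory; when given, stage outputs are written
#'   (counts/matrix TSV, loci BED, genes GTF, sets GMT, per-comparison
#'   results TSV, DMR BED, associations TSV, enrichment TSV, Ct CSV,
#'   manifest JSON).
#' @param n_perm permutations for the correction stage (0 disables).
#' @param run_enrichment,run_expression stage switches; disabling a stage
#'   leaves upstream outputs unchanged.
#' @param thresholds list of analysis thresholds: `min_abs_delta` (30),
#'   `max_p` (0.005), `min_loci` (4), `max_gap` (10000), `upstream` /
#'   `downstream` (10000), `n_enrich_samples` (10000).
#' @return list with `counts`, `truth`, `matrix`, `qc`, per-comparison
#'   `comparisons` (results, candidates, direction, dmrs, associations,
#'   gene summary), `overlaps` (loci and genes), `enrichment`,
#'   `expression`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, n_perm = 0,
                         run_enrichment = TRUE, run_expression = TRUE,
                         thresholds = list()) {
  stopifnot(inherits(config, "sim_config"))
  thr <- utils::modifyList(list(min_abs_delta = 30, max_p = 0.005,
                                min_loci = 4, max_gap = 10000,
                                upstream = 10000, downstream = 10000,
                                n_enrich_samples = 10000), thresholds)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   paste0(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  say("simulate: loci")
  loci <- generate_loci(config)
  say("simulate: counts for ", nrow(loci), " loci")
  sim <- generate_counts(config, loci)
  genes <- generate_annotation(config, loci)
  gene_sets <- generate_gene_sets(config, genes)

  say("score + QC")
  mat <- compute_scores(sim$counts)
  conf <- compute_confidence(sim$counts)
  qc <- sample_qc(mat)
  flagged <- qc[flagged == TRUE, sample]
  if (length(flagged)) {
    say("dropping flagged sample(s): ", paste(flagged, collapse = ", "))
    mat <- drop_samples(mat, flagged)
  }

  control <- config$control_group
  exposed <- setdiff(names(config$groups), control)
  win <- build_windows(genes, upstream = thr$upstream,
                       downstream = thr$downstream)
  comparisons <- list()
  for (g in exposed) {
    say("comparison ", control, "/", g)
    grp_samples <- mat$samples[group %in% c(control, g), sample]
    fm <- filter_loci(mat, conf, samples = grp_samples)
    res <- loci_t_test(fm, control, g, min_abs_delta = thr$min_abs_delta,
                       max_p = thr$max_p)
    cand <- select_candidates(res, thr$min_abs_delta, thr$max_p)
    dir_enr <- if (nrow(cand) > 0 && nrow(res[candidate == FALSE]) > 0)
      direction_enrichment(res) else NULL
    if (n_perm > 0)
      res <- permutation_correction(fm, res, n_perm = n_perm,
                                    seed = config$seed + match(g, exposed))
    dmrs <- find_dmrs(res, min_loci = thr$min_loci, max_gap = thr$max_gap)
    assoc <- map_loci(res[testable == TRUE,
                          .(locus_id, chrom, start, end)], win)
    gsum <- gene_dm_summary(assoc, cand$locus_id)
    comparisons[[g]] <- list(
      filter_report = attr(fm, "filter_report"), results = res,
      candidates = cand, direction = dir_enr, dmrs = dmrs,
      dmr_genes = map_dmrs(dmrs, win, loci), associations = assoc,
      gene_summary = gsum)
  }

  say("overlap summaries")
  cand_loci <- lapply(comparisons, function(x) x$candidates$locus_id)
  cand_genes <- lapply(comparisons, function(x)
    x$gene_summary[differentially_methylated == TRUE, gene_id])
  overlaps <- list(loci = overlap_summary(cand_loci),
                   genes = overlap_summary(cand_genes))

  enrichment <- NULL
  if (run_enrichment) {
    say("set enrichment")
    site_counts <- stats::setNames(genes$n_hpaii_sites, genes$gene_id)
    enrichment <- lapply(names(comparisons), function(g) {
      dm <- cand_genes[[g]]
      if (length(dm) == 0) return(NULL)
      w <- compute_bias_weights(site_counts, dm)
      enrich_all(gene_sets, dm, w, n_samples = thr$n_enrich_samples,
                 seed = config$seed + 100 + match(g, names(comparisons)))
    })
    names(enrichment) <- names(comparisons)
  }

  expression <- NULL
  ct <- NULL
  if (run_expression) {
    say("expression stage")
    ct <- generate_ct_table(config)
    targets <- names(config$expression$target_folds)
    expression <- lapply(targets, function(tg)
      expression_analysis(ct, tg, config$expression$ref_gene,
                          calibrator_group = control))
    names(expression) <- targets
  }

  manifest <- list(
    tool = "helptagdm",
    version = as.character(utils::packageVersion("helptagdm")),
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    stage_seeds = list(loci = stage_seed(config, "loci"),
                       counts = stage_seed(config, "counts"),
                       annotation = stage_seed(config, "annotation"),
                       gene_sets = stage_seed(config, "gene_sets"),
                       ct = stage_seed(config, "ct")),
    thresholds = thr, n_perm = n_perm,
    n_loci = nrow(loci), n_genes = nrow(genes),
    n_samples = nrow(sim$counts$samples),
    flagged_samples = flagged,
    comparisons = lapply(comparisons, function(x)
      list(n_testable = x$filter_report$n_retained,
           n_candidates = nrow(x$candidates), n_dmrs = nrow(x$dmrs))),
    log = log_lines)

  out <- list(config = config, loci = loci, counts = sim$counts,
              truth = sim$truth, genes = genes, gene_sets = gene_sets,
              matrix = mat, confidence = conf, qc = qc,
              comparisons = comparisons, overlaps = overlaps,
              enrichment = enrichment, expression = expression,
              ct_table = ct, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outdir, ...)
    write_counts_tsv(sim$counts, fp("counts.tsv"))
    data.table::fwrite(sim$truth, fp("truth.tsv"), sep = "\t")
    write_matrix_tsv(mat, fp("methylation_matrix.tsv"))
    write_loci_bed(loci, fp("loci.bed"))
    write_genes_gtf(genes, fp("genes.gtf"))
    write_gmt(gene_sets, fp("gene_sets.gmt"))
    data.table::fwrite(qc, fp("sample_qc.tsv"), sep = "\t")
    for (g in names(comparisons)) {
      cmp <- comparisons[[g]]
      data.table::fwrite(cmp$results, fp(sprintf("results_%s.tsv", g)),
                         sep = "\t")
      write_dmrs_bed(cmp$dmrs, fp(sprintf("dmrs_%s.bed", g)))
      data.table::fwrite(cmp$associations,
                         fp(sprintf("gene_associations_%s.tsv", g)),
                         sep = "\t")
      if (run_enrichment && !is.null(enrichment[[g]]))
        data.table::fwrite(enrichment[[g]],
                           fp(sprintf("enrichment_%s.tsv", g)), sep = "\t")
    }
    if (run_expression) {
      data.table::fwrite(ct, fp("ct_table.csv"))
      folds <- data.table::rbindlist(lapply(names(expression), function(tg)
        cbind(gene = tg, expression[[tg]]$groups)))
      data.table::fwrite(folds, fp("expression_folds.tsv"), sep = "\t")
    }
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [sim_config()] arguments; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$groups)) y$groups <- unlist(y$groups)
  if (!is.null(y$direction_by_group))
    y$direction_by_group <- unlist(y$direction_by_group)
  do.call(sim_config, y)
}
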