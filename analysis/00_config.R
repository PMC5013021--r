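# Shared study configuration for the analysis scripts.
#
# The defaults of sim_config() are the study conditions: four groups
# (Con n=5, UN n=6, ON n=5, Old n=6), ~100k HpaII loci at 2 kb mean
# spacing over 4 x 50 Mb chromosomes, score SD 10, spiked effects of 30
# score units (UN hypermethylating, Old hypomethylating, ON mixed), five
# 6-locus DMR blocks per exposed group and 24 loci spiked in all three
# exposed groups. Everything downstream is deterministic given this seed.

library(helptagdm)

STUDY_SEED <- 101
CONFIG <- sim_config(seed = STUDY_SEED)
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# deterministic regeneration of the shared upstream objects; cheap enough
# (~seconds) that each script rebuilds what it needs instead of passing
# binary state between scripts
study_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      loci <- generate_loci(CONFIG)
      sim <- generate_counts(CONFIG, loci)
      cache <<- list(loci = loci, counts = sim$counts, truth = sim$truth)
    }
    cache
  }
})

study_matrix <- function(d = study_data()) {
  list(matrix = compute_scores(d$counts),
       confidence = compute_confidence(d$counts))
}

study_comparison <- function(exposed, m = study_matrix()) {
  grp <- m$matrix$samples[group %in% c(CONFIG$control_group, exposed),
                          sample]
  fm <- filter_loci(m$matrix, m$confidence, samples = grp)
  res <- loci_t_test(fm, CONFIG$control_group, exposed)
  list(filtered = fm, results = res,
       report = attr(fm, "filter_report"))
}
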