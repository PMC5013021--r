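---
title: "Differential methylation from two-enzyme tag counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation from two-enzyme tag counts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helptagdm)
```

`helptagdm` implements a complete differential DNA-methylation analysis for
a two-enzyme restriction-and-sequencing assay (HELP-tagging): genomic DNA is
digested in parallel with methylation-sensitive *HpaII* and its
methylation-insensitive isoschizomer *MspI*, both cutting CCGG, and
sequencing tag counts at each CCGG locus are compared. Where a locus is
methylated, *HpaII* cannot cut and its tag count drops; *MspI* cuts
regardless and serves as the per-locus reference. This vignette explains
the models behind each stage, the tunable parameters, the design decisions
taken where the methodology was genuinely open, and what the synthetic
validation data can and cannot show.

## The methylation score

For locus $i$ in sample $s$ the score is a normalized density ratio on a
0–100 scale,

$$ \mathrm{score}_{is} = 100 \cdot \min\!\left(1,\;
   \frac{h_{is}/H_s}{r_i/R}\right), $$

where $h_{is}$ is the *HpaII* tag count, $H_s$ a per-sample depth
normalizer, $r_i$ the *MspI* reference count at the locus (here: the
pooled *MspI* count across samples) and $R$ its total. A score of 0 means
fully methylated (no *HpaII* cutting), 100 unmethylated (*HpaII* density
matches the reference). The ratio is capped at 100 because sampling noise
can push the *HpaII* density past the reference; the scale is bounded by
construction. Loci with $r_i = 0$ are unscorable and carried as `NA`.

**Choice of $H_s$.** Any density normalized by the *observed* total of a
methylation-sensitive digest is rescaled by the sample's genome-wide
unmethylated fraction: if half the genome is methylated, the observed
library is half the size and every density doubles. `compute_scores()`
therefore prefers explicit per-sample depth scale factors carried in the
sample sheet (the yield the library would have at full digestion, i.e. on
the *MspI* scale) and falls back to observed column sums only when they
are absent, with the caveat documented. The synthetic generator emits
calibrated factors, which is what an upstream scoring pipeline that
calibrates against the *MspI* reference produces.

## Confidence and locus filtering

Reliability of a score depends on both enzymes' local depth. The
confidence of locus $i$ in sample $s$ is

$$ c_{is} = \frac{r_i}{R}\,\bar S\,\bigl(1 - e^{-(h_{is}+m_{is})}\bigr), $$

with $\bar S$ the mean per-sample depth and $m_{is}$ the sample's *MspI*
count — monotone non-decreasing in both counts, near zero when the locus
is effectively unobserved in that sample.

A locus enters a comparison only if every sample of both compared groups
passes the confidence rule. Two readings of "confidence below the expected
mean" are implemented:

* **global** (default): a sample fails the locus when
  $c_{is} < f \cdot \bar c$, with $\bar c$ the mean confidence over the
  whole assay and $f = 1$. This removes systematically under-covered loci
  and reproduces the heavy attrition seen in real two-enzyme data, where
  roughly half of the ~1.6 M assayable CCGG loci are not reliably
  measurable in all samples; on the default synthetic data about 60% of
  loci are removed. Because the threshold is computed from the full
  confidence matrix, filtering is idempotent.
* **per-locus**: a sample fails when it falls below half of *that locus's*
  own mean confidence — an adaptive rule that catches a single dropout
  sample at an otherwise well-covered locus, but leaves systematic
  low-coverage loci in.

The global rule is the default because the filtering it produces matches
what the assay's published analyses actually did to their locus counts;
the per-locus rule is retained as a mode. This choice also matters
statistically: low-depth loci carry counting noise that cannot be
calibrated away, and removing them is what makes the realized per-locus
score SD match the nominal value the power calculation assumes.

**Sample QC.** A degraded *HpaII* library shows up as an excess of
zero scores. A sample is flagged when its zero-score fraction exceeds the
across-sample median by more than 3 robust MADs; flagged samples are
excluded before testing. On clean synthetic data this flags nothing; a
synthetically corrupted library is flagged reliably.

## Per-locus testing and candidate loci

Each exposed group is compared to the young control group (Con/UN, Con/ON,
Con/Old) with an equal-variance pooled two-sided t-test per locus
(vectorized; Welch available by argument). The effect
$\Delta = \bar x_{\mathrm{exposed}} - \bar x_{\mathrm{control}}$ is on the
score scale, so $\Delta < 0$ is hypermethylation (toward 0 = methylated)
and $\Delta > 0$ hypomethylation. This sign convention is fixed repo-wide.
Loci with fewer than two values in a group, or no variance and no mean
difference, are reported untestable rather than dropped.

Candidate ("loci of interest") gates are strict inequalities:
$|\Delta| > 30$ score units **and** $p < 0.005$.

```{r}
power_analytic(5, 5, sd = 10, delta = 30, alpha = 0.005)
power_analytic(5, 6, sd = 10, delta = 30, alpha = 0.005)
```

**Power calibration.** At the calibration point (per-group SD 10, effect
30, $\alpha = 0.005$) the analytic noncentral-t power for a balanced
$n{=}5$ design is 77.5% (df 8, noncentrality 4.74) — just under the 80%
often quoted for this design. At the study's actual group sizes (5 vs 6)
it is 85.0%. `power_simulation()` estimates the same quantity by Monte
Carlo and agrees with the closed form within Monte-Carlo error; the
package reports both configurations.

**The two gates interact.** The power above is the probability of passing
the *p*-gate. When the true effect sits exactly at the 30-point delta
gate, the observed $|\hat\Delta|$ exceeds 30 only about half the time, so
the probability of passing *both* gates is roughly half the *p*-gate
power. Sensitivity statements in the tests are therefore made on the
*p*-gate, the quantity the power calculation predicts.

## Permutation correction

Group labels are permuted (400 times by default) and the per-locus
p-values of all permutations are pooled into a single null distribution; a
candidate is significant after correction iff its observed p-value lies at
or below the 2.5th percentile of that pooled distribution (two-tailed
0.05). Three remarks:

* The alternative literal reading — "p-values in the *largest* 97.5% of
  the permuted distribution" — would declare nearly every locus
  significant and is rejected.
* A pooled (across loci) null is used rather than per-locus nulls: a few
  hundred permutations cannot resolve per-locus p-values anywhere near
  0.005.
* Because the pooled null of a well-behaved assay is approximately
  uniform, its 2.5th percentile sits near 0.025 — above the 0.005
  candidate gate — so the correction rarely removes a gated candidate.
  That is the expected behaviour of this rule, not a defect, and matches
  how such corrections have been reported (all candidates preserved).

When the two groups admit few distinct label assignments they are
enumerated and sampled without replacement ($\binom{10}{5} = 252$ for two
groups of five — fewer than 400, in which case sampling falls back to
with-replacement and the distinct count is logged); with larger designs
random shuffles are used.

## DMR calling

A differentially methylated region is a maximal run of at least 4
candidate loci that are **consecutive in the testable-locus ordering**,
with at most 10 kb between adjacent members and a uniform direction of
change. "Consecutive" is read literally: an intervening tested-but-not-
candidate locus breaks the run (a gap-only mode is available), untestable
loci do not. Coordinates span the first to last member locus. The caller
is linear-time; an independent quadratic enumerator (`dmr_oracle()`)
exists purely for verification and the two are property-tested for
equivalence on thousands of random fixtures.

Under the default study conditions (effect exactly at the delta gate) a
spiked 6-locus block passes *all* single-locus gates only rarely — each
member clears the delta gate with probability about one half — so
end-to-end block recovery is asserted for the blocks that are fully gated,
and separately exercised with a stronger spike where full gating is the
rule rather than the exception.

## Gene mapping

Genes are mapped through windows in transcription orientation. The default
window runs from 10 kb upstream of the TSS to 10 kb downstream of the gene
body end; a stricter variant (`mode = "methods"`) stops at the
transcription end site. Coordinates are 0-based half-open throughout
(GTF is converted on read); overlap at the window end is exclusive. A
locus may map to several overlapping genes; a DMR maps wherever any member
locus maps. The broader window is the default because it is the rule the
reported gene counts in this assay family correspond to.

## Bias-corrected set enrichment

Genes with more assayed *HpaII* sites are more likely to contain a
candidate locus by chance, biasing naive set enrichment. Following the
probability-weighting idea of GOseq-style corrections, genes are binned by
site-count quantiles (10 bins by default) and each gene's sampling weight
is the empirical rate of differential methylation in its bin (floored by a
half-count pseudo-rate, normalized over the universe). A quantile-binned
empirical weight replaces the spline-based weighting function of the
original method — at a few thousand genes a spline adds nothing but
smoothing parameters.

Enrichment p-values come from weighted random sampling: draw
$|\mathrm{DM}|$ genes without replacement with probability proportional to
the weights, $10^4$ times, and compare overlaps with the observed one.
Add-one estimators $(1 + k)/(n + 1)$ avoid zero p-values, so the smallest
attainable p is $1/(n+1)$. With uniform weights the sampled p-values
converge to hypergeometric tails, which is how the machinery is verified.
No multiple-testing correction is applied across sets; raw enrichment
p-values are reported.

## Relative expression (2^-ddCt)

Per animal, replicate Ct values are averaged per gene;
$\Delta Ct = \overline{Ct}_{\mathrm{target}} - \overline{Ct}_{\mathrm{ref}}$
(reference gene *Rps3* by default);
$\Delta\Delta Ct$ subtracts the calibrator group's mean $\Delta Ct$; fold
change is $2^{-\Delta\Delta Ct}$. Plate- or loading-level shifts common to
both genes cancel exactly. Group differences are tested by one-way ANOVA
with Tukey's HSD — on the $\Delta Ct$ scale, where the quantity is closer
to normal with homogeneous variance, while folds are reported on the
$2^{-\Delta\Delta Ct}$ scale. Replicate outlier handling is deliberately
absent by default.

## The synthetic generator

The generator emulates the study design: groups Con (n=5), UN (n=6),
ON (n=5), Old (n=6); loci spaced with exponential gaps of mean 2 kb (the
average CCGG spacing in a mammalian genome); a bimodal baseline score
distribution with components near 15 and 85 (CpG-island-like bimodality,
weights 0.45/0.55, per-locus jitter SD 5); per-group score SD of 10.
Differential loci (1% per exposed group by default) are spiked by 30 score
units — UN hypermethylating, Old hypomethylating, ON mixed with no net
shift — plus five contiguous 6-locus DMR blocks per exposed group and 24
loci spiked coherently in all three exposed groups. Spikes are only placed
where they cannot push a mean outside [0, 100].

Counts follow the simplest over-dispersed tag-counting model: per-locus
sequencing propensities are gamma-distributed (negative-binomial *MspI*
counts across loci, dispersion `nb_size`), *HpaII* counts are Poisson with
expectation proportional to depth × propensity × score/100. Mean *MspI*
depth is 300 reads per locus per sample; depth is a free knob of the
assay, not a reported value. Per-sample library sizes vary ±20%.

**Noise calibration.** The realized score at a locus carries both
biological spread and counting noise with variance
$\approx 100\,\mu/d_i$ at score $\mu$ and full-digestion depth $d_i$. The
generator draws true scores with
$\sigma^2_{\mathrm{bio}} = \max(\sigma^2 - 100\,\mu/d_i,\ (\sigma/4)^2)$
so the *realized* per-group SD matches the configured `score_sd` — this is
the generator's contract, not a tuning knob. At loci too shallow for the
subtraction the floor applies and the realized SD exceeds the target;
those are exactly the loci the confidence filter removes.

**What it does not emulate:** read-level artefacts (adapters, mapping),
batch and litter effects, spatial correlation of methylation outside the
spiked blocks, cell-composition shifts in tissue, CpG-density-dependent
coverage, and any relationship between methylation and expression (the Ct
generator is driven by configured fold changes, not by the methylation
truth). Passing tests on this data therefore validate the statistical
machinery and its calibration, not biological discovery performance on
real livers.

**Problem sizes in the test-suite.** The full-scale checks run on the
default genome (~100k loci × 22 samples, seconds per stage); oracle
equivalences use thousands of small random fixtures; enrichment checks use
$10^4$ draws per configuration. All randomness is seeded; identical
(config, seed) pairs reproduce outputs bit-identically.

## Numerical and interface choices

* Scores are clipped to [0, 100]; true spiked means are placed so clipping
  is negligible at spiked loci (boundary components shave under one score
  unit off a 30-unit spike).
* Candidate gates use strict inequalities (`> 30`, `< 0.005`).
* Ties in the permutation null are counted conservatively (observed ≤
  threshold).
* `find_dmrs()` refuses unsorted input rather than silently re-sorting.
* Intervals are 0-based half-open internally; GTF (1-based inclusive) is
  converted at the boundary by `rtracklayer`.
* Group-size combinatorics: enumerated assignments when
  $\binom{n}{n_1} \le 5000$, random shuffles otherwise.
* The control group is the calibrator and comparator throughout; no age
  covariate is modelled for the Old comparison.

## Known limitations

The confidence formula and its threshold reading are reconstructions of a
procedure whose exact form is not public; both implemented readings
preserve the documented monotone dependence on the two enzymes' totals,
and the global reading is preferred because it reproduces the observed
locus attrition. The permutation correction, as specified, is inactive for
loci already past the 0.005 gate. Fold-change SEMs are arithmetic on the
fold scale (matching how such tables are reported) although the test runs
on the log scale. The enrichment stage assumes the DM gene set is small
relative to the universe; weights are recomputed per comparison.
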