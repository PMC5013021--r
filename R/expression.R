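#' Relative expression by the 2^-ddCt method
#'
#' Per animal, replicate Ct values are averaged per gene; dCt = mean
#' Ct(target) - mean Ct(reference gene); ddCt = dCt - mean dCt over the
#' calibrator group's animals; fold change = 2^-ddCt. The calibrator
#' group's mean fold is 1 by construction (up to the geometric/arithmetic
#' averaging distinction; its mean ddCt is exactly 0). Group means and
#' standard errors of the fold changes are reported.
#'
#' @param ct_table data.table with `animal_id`, `group`, `gene`,
#'   `replicate`, `ct` (cycles).
#' @param target_gene gene to quantify.
#' @param ref_gene normalization reference (default `"Rps3"`).
#' @param calibrator_group group whose mean dCt anchors ddCt = 0.
#' @return list of class `expression_result`: `per_animal` (animal-level
#'   dct/ddct/fold), `groups` (per group: `mean_fold`, `sem_fold`, `n`),
#'   `target_gene`, `ref_gene`, `calibrator_group`.
#' @export
ddct_fold_change <- function(ct_table, target_gene, ref_gene = "Rps3",
                             calibrator_group) {
  ct <- data.table::as.data.table(ct_table)
  if (!ref_gene %in% ct$gene) stop("reference gene absent: ", ref_gene)
  if (!target_gene %in% ct$gene) stop("target gene absent: ", target_gene)
  if (!calibrator_group %in% ct$group)
    stop("calibrator group absent: ", calibrator_group)
  sub <- ct[gene %in% c(target_gene, ref_gene)]
  mean_ct <- sub[, .(mct = mean(ct)), by = .(animal_id, group, gene)]
  wide <- data.table::dcast(mean_ct, animal_id + group ~ gene,
                            value.var = "mct")
  if (anyNA(wide[[target_gene]]) || anyNA(wide[[ref_gene]]))
    stop("every animal needs Ct values for both target and reference gene")
  wide[, dct := get(target_gene) - get(ref_gene)]
  cal <- wide[group == calibrator_group, mean(dct)]
  wide[, ddct := dct - cal]
  wide[, fold := 2^(-ddct)]
  groups <- wide[, .(mean_fold = mean(fold),
                     sem_fold = stats::sd(fold) / sqrt(.N), n = .N),
                 by = group]
  structure(list(per_animal = wide[, .(animal_id, group, dct, ddct, fold)],
                 groups = groups[], target_gene = target_gene,
                 ref_gene = ref_gene, calibrator_group = calibrator_group),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("2^-ddCt fold changes: %s vs %s, calibrator %s\n",
              x$target_gene, x$ref_gene, x$calibrator_group))
  print(x$groups)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD
#'
#' Fixed-effects one-way ANOVA followed by Tukey's honest significant
#' difference test over all group pairs (studentized-range distribution,
#' via [stats::TukeyHSD()]).
#'
#' @param values numeric response (one value per animal).
#' @param groups factor/character group labels, same length.
#' @return list: `anova_f`, `anova_p`, `df` (between, within), `tukey`
#'   (data.table: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  wss <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  if (all(wss == 0)) stop("zero within-group variance everywhere")
  fit <- stats::aov(values ~ groups)
  at <- stats::anova(fit)
  th <- stats::TukeyHSD(fit)$groups
  tukey <- data.table::data.table(comparison = rownames(th),
                                  diff = th[, "diff"], lwr = th[, "lwr"],
                                  upr = th[, "upr"], p_adj = th[, "p adj"])
  list(anova_f = at$`F value`[1], anova_p = at$`Pr(>F)`[1],
       df = c(between = at$Df[1], within = at$Df[2]), tukey = tukey)
}

#' Full relative-expression analysis of one gene
#'
#' Combines [ddct_fold_change()] with a one-way ANOVA + Tukey HSD across
#' groups. The test is run on the animal-level dCt values (the
#' log-scale quantity, statistically better behaved than the folds);
#' fold changes are reported on the 2^-ddCt scale.
#'
#' @inheritParams ddct_fold_change
#' @return `expression_result` with `anova` element added.
#' @export
expression_analysis <- function(ct_table, target_gene, ref_gene = "Rps3",
                                calibrator_group) {
  res <- ddct_fold_change(ct_table, target_gene, ref_gene, calibrator_group)
  res$anova <- anova_tukey(res$per_animal$dct, res$per_animal$group)
  res
}
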