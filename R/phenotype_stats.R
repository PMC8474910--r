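# Strain-group fitness contrasts: across-strain heterogeneity, gene-set
# defined group tests on strain medians, bacterial-load-adjusted linear
# models, and the supplementation contrast on relative offspring numbers.

#' Assign strains to groups by joint presence of a gene set
#'
#' A strain is in the positive group iff it carries every gene of the set
#' (all-of semantics), mirroring how a complete biosynthesis pathway
#' defines a phenotype-relevant strain class. The default set is the
#' thiamine biosynthesis pathway genes.
#'
#' @param pa presence/absence matrix (genes x strains).
#' @param gene_set character vector of gene ids; every id must be a row of
#'   `pa`.
#' @param labels length-2 character vector: positive label (complete set
#'   carried) and negative label.
#' @return named character vector strain -> group label, with the positive
#'   label in `attr(, "positive")`.
#' @export
assign_groups <- function(pa, gene_set = c("thiC", "thiD", "thiO",
                                           "thiS", "thiG", "thiE"),
                          labels = c("TBP+", "TBP-")) {
  missing <- setdiff(gene_set, rownames(pa))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  complete <- colSums(pa[gene_set, , drop = FALSE] == 1L) == length(gene_set)
  out <- stats::setNames(ifelse(complete, labels[1L], labels[2L]),
                         colnames(pa))
  attr(out, "positive") <- labels[1L]
  out
}

#' Across-strain heterogeneity of offspring number
#'
#' Kruskal-Wallis rank test of replicate offspring counts across strains
#' (ties-corrected statistic, chi-squared approximation). Being rank-based,
#' the result is invariant under strictly monotone transforms of the
#' counts.
#'
#' @param pheno replicate-level phenotype table.
#' @return `htest` object from [stats::kruskal.test()].
#' @export
kruskal_across_strains <- function(pheno) {
  tab <- table(pheno$strain)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 strains with at least 2 replicates")
  stats::kruskal.test(pheno$offspring, factor(pheno$strain))
}

#' Two-group contrast on strain medians
#'
#' Reduces each strain to its median value first (the strain, not the
#' replicate vial, is the experimental unit), then applies a two-sided
#' Mann-Whitney test between the groups: exact null distribution when the
#' total number of strains is at most 20 and there are no ties, normal
#' approximation otherwise.
#'
#' @param pheno replicate-level phenotype table.
#' @param groups named vector strain -> group label with exactly 2 levels
#'   among the analysis strains (see [assign_groups()]).
#' @param value phenotype column to test (default `"offspring"`; use
#'   `"weight"` for the crowding check).
#' @return `htest` object from [stats::wilcox.test()], with the strain
#'   medians attached as `attr(, "strain_medians")`.
#' @export
group_median_test <- function(pheno, groups, value = "offspring") {
  med <- strain_medians(pheno, value)
  g <- groups[names(med)]
  if (any(is.na(g)))
    stop("no group assignment for strain(s): ",
         paste(names(med)[is.na(g)], collapse = ", "))
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("exactly two groups required, got ",
                              length(lev))
  x <- med[g == lev[1L]]
  y <- med[g == lev[2L]]
  if (length(x) == 0L || length(y) == 0L) stop("a group is empty")
  n_tot <- length(med)
  ht <- stats::wilcox.test(x, y, exact = n_tot <= 20L,
                           correct = n_tot > 20L)
  attr(ht, "strain_medians") <- med
  ht
}

#' Offspring model adjusted for bacterial load
#'
#' Linear model of replicate offspring on strain identity with
#' log10(CFU + 1)-transformed bacterial load as covariate. Reports the
#' sequential ANOVA p-value of the strain term after the load term (does
#' strain matter once load is accounted for?) and, from a load-only model,
#' the p-value of load alone. Replicates without a CFU measurement are
#' dropped with a message.
#'
#' @param pheno replicate-level phenotype table with a `cfu` column.
#' @return list with `strain_p`, `load_only_p`, the fitted models `model`
#'   and `load_model`, and `transform` (the load scale used).
#' @export
load_adjusted_model <- function(pheno) {
  if (!"cfu" %in% names(pheno)) stop("phenotype table has no cfu column")
  keep <- !is.na(pheno$cfu)
  if (!any(keep)) stop("all CFU values missing")
  if (any(!keep))
    message(sum(!keep), " replicate(s) without CFU dropped")
  d <- pheno[keep, , drop = FALSE]
  d$log_load <- log10(d$cfu + 1)
  d$strain <- factor(d$strain)
  one_strain <- nlevels(d$strain) < 2L
  if (one_strain)
    message("single strain: no strain term to test")
  full <- if (one_strain) stats::lm(offspring ~ log_load, data = d)
          else stats::lm(offspring ~ log_load + strain, data = d)
  load_only <- stats::lm(offspring ~ log_load, data = d)
  an <- stats::anova(full)
  list(
    strain_p = if (one_strain) NA_real_ else an["strain", "Pr(>F)"],
    load_only_p = summary(load_only)$coefficients["log_load", "Pr(>|t|)"],
    model = full,
    load_model = load_only,
    transform = "log10(cfu + 1)"
  )
}

#' Supplementation contrast on relative offspring numbers
#'
#' For each treatment arm, the replicate offspring counts of the
#' non-control strains are divided by the mean offspring of the control
#' group (the strains carrying the complete pathway) in the same arm; a
#' value of 1 means parity. The treatment effect on these ratios is tested
#' with a linear mixed-effects model (REML) with treatment as fixed effect
#' and strain as random intercept; p-values use the containment
#' (inner-outer) degrees of freedom of [nlme::lme()].
#'
#' @param pheno replicate-level phenotype table with a `treatment` column
#'   holding exactly two levels.
#' @param groups named vector strain -> group label (see
#'   [assign_groups()]).
#' @param control group label acting as denominator; defaults to
#'   `attr(groups, "positive")`.
#' @param ref treatment level used as reference (intercept) of the fixed
#'   effect; default is the alphabetically first level, so
#'   `treatment_effect` is the second level's shift in relative offspring.
#' @return list with `values` (the per-replicate relative offspring
#'   table), `treatment_p`, `treatment_effect` (fixed-effect estimate for
#'   the second treatment level), `cell_means` (strain x treatment means
#'   with standard errors), and the fitted `model`.
#' @export
relative_offspring_contrast <- function(pheno, groups,
                                        control = attr(groups, "positive"),
                                        ref = NULL) {
  if (!"treatment" %in% names(pheno))
    stop("phenotype table has no treatment column")
  if (is.null(control)) stop("control group label must be given")
  arms <- sort(unique(pheno$treatment))
  if (length(arms) != 2L)
    stop("exactly two treatment levels required, got ", length(arms))
  g <- groups[pheno$strain]
  if (any(is.na(g)))
    stop("no group assignment for strain(s): ",
         paste(unique(pheno$strain[is.na(g)]), collapse = ", "))
  rel <- do.call(rbind, lapply(arms, function(a) {
    arm <- pheno[pheno$treatment == a, , drop = FALSE]
    garm <- groups[arm$strain]
    ctrl <- arm$offspring[garm == control]
    if (length(ctrl) == 0L)
      stop("no control-group replicates in treatment arm '", a, "'")
    denom <- mean(ctrl)
    if (denom <= 0) stop("control mean is zero in treatment arm '", a, "'")
    test <- arm[garm != control, , drop = FALSE]
    if (nrow(test) == 0L)
      stop("no non-control replicates in treatment arm '", a, "'")
    data.frame(strain = test$strain, treatment = a,
               value = test$offspring / denom,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ref)) {
    if (!ref %in% arms) stop("ref is not a treatment level: ", ref)
    arms <- c(ref, setdiff(arms, ref))
  }
  rel$treatment <- factor(rel$treatment, levels = arms)
  if (stats::sd(rel$value) == 0) {
    # exact parity in every batch: nothing for the mixed model to estimate
    message("all relative offspring values identical; treatment effect is 0")
    fit <- NULL
    treatment_p <- 1
    treatment_effect <- 0
  } else {
    fit <- nlme::lme(value ~ treatment, random = ~ 1 | strain, data = rel,
                     method = "REML")
    tt <- summary(fit)$tTable
    fx_row <- grep("^treatment", rownames(tt))
    treatment_p <- unname(tt[fx_row, "p-value"])
    treatment_effect <- unname(tt[fx_row, "Value"])
  }
  agg <- stats::aggregate(value ~ strain + treatment, data = rel,
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  cell_means <- cbind(agg[c("strain", "treatment")],
                      as.data.frame(agg$value))
  list(
    values = rel,
    treatment_p = treatment_p,
    treatment_effect = treatment_effect,
    cell_means = cell_means,
    model = fit
  )
}

#' Fold difference in mean offspring between two strains
#'
#' Ratio of the larger to the smaller strain mean (>= 1 by convention); the
#' orientation reports which strain is on top. A zero denominator is
#' reported as infinite with a flag.
#'
#' @param pheno replicate-level phenotype table.
#' @param strain_a,strain_b strain ids, each with at least one replicate.
#' @return list with `fold` (>= 1 or Inf), `higher` (strain id with the
#'   larger mean), `means` (named vector), `zero_denominator` (logical).
#' @export
fold_difference <- function(pheno, strain_a, strain_b) {
  m <- strain_means(pheno)
  for (s in c(strain_a, strain_b))
    if (!s %in% names(m)) stop("strain not in phenotype table: ", s)
  a <- m[[strain_a]]; b <- m[[strain_b]]
  hi <- if (a >= b) strain_a else strain_b
  lo_val <- min(a, b)
  list(
    fold = if (lo_val == 0) Inf else max(a, b) / lo_val,
    higher = hi,
    means = c(stats::setNames(a, strain_a), stats::setNames(b, strain_b)),
    zero_denominator = lo_val == 0
  )
}
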