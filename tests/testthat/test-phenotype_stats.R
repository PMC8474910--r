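# Small deterministic phenotype tables used across contrasts.
two_group_pheno <- function() {
  # three low strains, three high strains, three replicates each
  means <- c(L1 = 10, L2 = 11, L3 = 12, H1 = 20, H2 = 21, H3 = 22)
  constant_pheno(means)
}

test_that("across-strain heterogeneity matches the hand-ranked statistic", {
  ph <- data.frame(strain = rep(c("a", "b"), each = 3),
                   replicate = rep(c("r1", "r2", "r3"), 2),
                   offspring = c(1L, 2L, 3L, 4L, 5L, 6L))
  kt <- kruskal_across_strains(ph)
  expect_equal(unname(kt$statistic), 3.857, tolerance = 1e-3)
  # identical groups: tie-corrected statistic at its minimum, p in the ~1 region
  ph2 <- ph; ph2$offspring <- rep(c(1L, 2L, 3L), 2)
  kt2 <- kruskal_across_strains(ph2)
  expect_equal(unname(kt2$statistic), 0)
  expect_gt(kt2$p.value, 0.95)
  expect_error(kruskal_across_strains(ph[1:4, ]), "at least 2 strains")
})

test_that("heterogeneity p-value drops as causal effects grow", {
  pvals <- sapply(c(0, 20), function(b) {
    cfg <- sim_config(n_strains = 17, n_genes = 100, causal_beta = b,
                      tau = 2, replicates = 8, seed = 3)
    tree <- simulate_strain_tree(17, seed = 3)
    pa <- simulate_presence_absence(tree, cfg)
    ph <- simulate_phenotypes(pa, cfg)
    kruskal_across_strains(ph)$p.value
  })
  expect_lt(pvals[2], pvals[1])
})

test_that("group contrast on strain medians uses the exact null for small n", {
  ph <- two_group_pheno()
  groups <- c(L1 = "TBP-", L2 = "TBP-", L3 = "TBP-",
              H1 = "TBP+", H2 = "TBP+", H3 = "TBP+")
  ht <- group_median_test(ph, groups)
  # U at its extreme: 2 of the C(6,3)=20 orderings are as extreme, p = 0.1
  expect_equal(ht$p.value, 0.1)
  expect_equal(attr(ht, "strain_medians")[["H3"]], 22)
  # symmetric compositions sit at the centre of the null
  ph_sym <- constant_pheno(c(X1 = 10, X2 = 11, X3 = 12,
                             Y1 = 10, Y2 = 11, Y3 = 12))
  g2 <- c(X1 = "g1", X2 = "g1", X3 = "g1", Y1 = "g2", Y2 = "g2", Y3 = "g2")
  expect_gt(suppressWarnings(group_median_test(ph_sym, g2))$p.value, 0.9)
  expect_error(group_median_test(ph, groups[1:3]), "no group assignment")
})

test_that("the exact Mann-Whitney null is used at the study's group sizes", {
  # n = 17 split 11/6: exact distribution vs full enumeration at the extreme
  med <- c(30:40, 10:15)   # distinct values, complete group separation
  strains <- sprintf("s%02d", 1:17)
  ph <- constant_pheno(setNames(med, strains))
  groups <- setNames(rep(c("TBP+", "TBP-"), c(11, 6)), strains)
  ht <- group_median_test(ph, groups)
  # complete separation: exactly 2 of choose(17,6) orderings as extreme
  expect_equal(ht$p.value, 2 / choose(17, 6), tolerance = 1e-10)
})

test_that("rank-based contrasts are invariant under monotone transforms", {
  ph <- two_group_pheno()
  groups <- c(L1 = "TBP-", L2 = "TBP-", L3 = "TBP-",
              H1 = "TBP+", H2 = "TBP+", H3 = "TBP+")
  ph2 <- ph
  ph2$offspring <- ph$offspring^2L   # strictly monotone on non-negatives
  expect_equal(group_median_test(ph, groups)$p.value,
               group_median_test(ph2, groups)$p.value)
  expect_equal(kruskal_across_strains(ph)$statistic,
               kruskal_across_strains(ph2)$statistic)
})

test_that("weight contrasts run through the same strain-median machinery", {
  ph <- two_group_pheno()
  set.seed(2)
  ph$weight <- rnorm(nrow(ph), 1, 0.05)   # no group structure
  groups <- c(L1 = "TBP-", L2 = "TBP-", L3 = "TBP-",
              H1 = "TBP+", H2 = "TBP+", H3 = "TBP+")
  ht <- group_median_test(ph, groups, value = "weight")
  expect_gt(ht$p.value, 0.05)
})

test_that("load-adjusted model separates strain signal from load noise", {
  set.seed(15)
  cfg <- sim_config(n_strains = 10, n_genes = 50, causal_beta = 20, tau = 5,
                    replicates = 8, seed = 15)
  tree <- simulate_strain_tree(10, seed = 15)
  pa <- simulate_presence_absence(tree, cfg)
  ph <- simulate_phenotypes(pa, cfg)   # cfu is pure noise by construction
  fit <- load_adjusted_model(ph)
  expect_lt(fit$strain_p, 0.01)
  expect_gt(fit$load_only_p, 0.01)
  expect_match(fit$transform, "log10")
  # offspring exactly proportional to load in one strain: R^2 -> 1
  ph1 <- data.frame(strain = "s1", replicate = sprintf("r%d", 1:12),
                    offspring = seq(10L, 120L, by = 10L))
  ph1$cfu <- 10^(ph1$offspring / 30) - 1
  fit1 <- suppressWarnings(suppressMessages(load_adjusted_model(ph1)))
  expect_gt(suppressWarnings(summary(fit1$load_model))$r.squared, 0.999)
  expect_true(is.na(fit1$strain_p))
  expect_error(load_adjusted_model(two_group_pheno()), "no cfu column")
})

test_that("permuted load gives calibrated load-only p-values", {
  cfg <- sim_config(n_strains = 10, n_genes = 50, causal_beta = 15,
                    replicates = 8, seed = 8)
  tree <- simulate_strain_tree(10, seed = 8)
  pa <- simulate_presence_absence(tree, cfg)
  ph <- simulate_phenotypes(pa, cfg)
  set.seed(21)
  pvals <- replicate(40, {
    ph$cfu <- sample(ph$cfu)
    load_adjusted_model(ph)$load_only_p
  })
  expect_gt(mean(pvals), 0.25)           # not systematically small
  expect_lt(mean(pvals < 0.1), 0.35)     # roughly uniform tail
})

# Builder for supplementation experiments: TBP- strains get `lift` x mean
# under treatment "+", controls stay flat; NB replicate noise.
supp_pheno <- function(lift, seed, r = 8, noise_size = 50) {
  set.seed(seed)
  ctrl <- c(P1 = 45, P2 = 48, P3 = 42)     # TBP+ controls
  test <- c(M1 = 30, M2 = 28, M3 = 33)     # TBP- strains
  rows <- list()
  for (trt in c("none", "thiamine")) {
    for (s in names(ctrl))
      rows[[paste(s, trt)]] <- data.frame(
        strain = s, replicate = sprintf("r%d", 1:r),
        offspring = rnbinom(r, mu = ctrl[[s]], size = noise_size),
        treatment = trt)
    for (s in names(test)) {
      mu <- test[[s]] * if (trt == "thiamine") lift else 1
      rows[[paste(s, trt)]] <- data.frame(
        strain = s, replicate = sprintf("r%d", 1:r),
        offspring = rnbinom(r, mu = mu, size = noise_size),
        treatment = trt)
    }
  }
  do.call(rbind, rows)
}

supp_groups <- function() {
  g <- c(P1 = "TBP+", P2 = "TBP+", P3 = "TBP+",
         M1 = "TBP-", M2 = "TBP-", M3 = "TBP-")
  attr(g, "positive") <- "TBP+"
  g
}

test_that("exact parity gives relative values of one and a zero effect", {
  ctrl_means <- c(P1 = 40, P2 = 40)
  rows <- list()
  for (trt in c("none", "thiamine")) {
    for (s in names(ctrl_means))
      rows[[paste(s, trt)]] <- data.frame(
        strain = s, replicate = c("r1", "r2"), offspring = 40L,
        treatment = trt)
    for (s in c("M1", "M2"))
      rows[[paste(s, trt)]] <- data.frame(
        strain = s, replicate = c("r1", "r2"), offspring = 40L,
        treatment = trt)
  }
  ph <- do.call(rbind, rows)
  g <- c(P1 = "TBP+", P2 = "TBP+", M1 = "TBP-", M2 = "TBP-")
  attr(g, "positive") <- "TBP+"
  res <- suppressMessages(relative_offspring_contrast(ph, g))
  expect_true(all(res$values$value == 1))
  expect_equal(res$treatment_effect, 0)
})

test_that("relative values are invariant to common scaling within an arm", {
  ph <- supp_pheno(lift = 1.3, seed = 6)
  ph2 <- ph
  dbl <- ph2$treatment == "thiamine"
  ph2$offspring[dbl] <- 2L * ph2$offspring[dbl]
  r1 <- relative_offspring_contrast(ph, supp_groups())
  r2 <- relative_offspring_contrast(ph2, supp_groups())
  expect_equal(r1$values$value, r2$values$value)
  expect_equal(r1$treatment_p, r2$treatment_p)
})

test_that("a 30% supplementation lift is recovered as a positive effect", {
  effects <- sapply(1:20, function(s) {
    res <- relative_offspring_contrast(supp_pheno(lift = 1.3, seed = s),
                                       supp_groups())
    res$treatment_effect
  })
  expect_gte(mean(effects > 0), 0.9)
  # and the mixed model structure is the declared one
  res <- relative_offspring_contrast(supp_pheno(1.3, 1), supp_groups())
  expect_s3_class(res$model, "lme")
  expect_true(all(c("strain", "treatment") %in% names(res$cell_means)))
  ph_one_arm <- supp_pheno(1.3, 1)
  ph_one_arm <- ph_one_arm[ph_one_arm$treatment == "thiamine", ]
  expect_error(relative_offspring_contrast(ph_one_arm, supp_groups()),
               "two treatment levels")
})

test_that("fold differences report magnitude and orientation", {
  ph <- constant_pheno(c(hi = 28, lo = 10, eq = 28))
  fd <- fold_difference(ph, "hi", "lo")
  expect_equal(fd$fold, 2.8)
  expect_equal(fd$higher, "hi")
  # symmetric call flips orientation, not magnitude
  fd2 <- fold_difference(ph, "lo", "hi")
  expect_equal(fd2$fold, 2.8)
  expect_equal(fd2$higher, "hi")
  expect_equal(fold_difference(ph, "hi", "eq")$fold, 1.0)
  fd0 <- fold_difference(constant_pheno(c(a = 5, z = 0)), "a", "z")
  expect_true(is.infinite(fd0$fold) && fd0$zero_denominator)
})

test_that("gene-set groups use all-of semantics over the matrix", {
  pa <- pa_mat(
    thiC = c(1L, 1L, 0L),
    thiD = c(1L, 0L, 0L),
    other = c(0L, 1L, 1L),
    strains = c("s1", "s2", "s3")
  )
  g <- assign_groups(pa, gene_set = c("thiC", "thiD"))
  expect_identical(unname(c(g)), c("TBP+", "TBP-", "TBP-"))
  expect_identical(attr(g, "positive"), "TBP+")
  expect_error(assign_groups(pa, gene_set = c("thiC", "thiX")),
               "not in matrix")
})
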