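---
title: "Phylogeny-aware pan-genome association with host fitness phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware pan-genome association with host fitness phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panphen)
```

## The problem

Closely related bacterial strains can confer very different fitness to an
animal host. When hosts are mono-associated with one strain at a time, the
strain is the experimental unit, and differences in a quantitative host
phenotype — here, the number of offspring produced over a fixed assay
window — can be attributed to differences in the strains' gene content.
`panphen` tests every gene cluster of a bacterial pan-genome for
association between its presence/absence pattern across strains and the
host phenotype, using the strain phylogeny to guard against the dominant
confounder of such screens: shared ancestry, which makes whole clades of
genes rise and fall together.

## The association score

For gene $g$, let $D_g$ be the difference between the mean phenotype of
strains carrying the gene and strains lacking it, $\sigma$ a global
standard deviation of the phenotype across strains, and $n_g$ the minimum
number of gain/loss events needed to produce the gene's presence/absence
pattern on the strain phylogeny. The score is

$$ S_g = \sqrt{n_g}\,\frac{D_g}{\sigma}. $$

$D_g/\sigma$ is a standardized effect; the $\sqrt{n_g}$ factor up-weights
genes whose pattern arose repeatedly on the tree. A gene confined to a
single clade ($n_g = 1$) can show a large $D_g$ purely because that clade
differs for unrelated reasons; a gene gained and lost several times that
still tracks the phenotype carries much stronger evidence. The score is
signed (positive when carriers do better) and its magnitude is invariant
under positive affine transforms of the phenotype, which the test-suite
asserts.

Two definitions of $\sigma$ are defensible and the choice is exposed as
`sigma_mode`: the default, `"strain_means"`, is the sample SD of per-strain
mean phenotype over the analysis strains (the strain is the unit of the
design, and $D_g$ is a contrast of exactly those means); `"replicates"`
pools all replicate-level values and yields systematically smaller scores
because within-strain noise inflates the denominator. Ranks are unaffected
by the choice. All package defaults and reported results use
`"strain_means"`, recorded in the result attributes.

## Counting gain/loss events

$n_g$ is computed by unit-cost parsimony (a Sankoff dynamic program
vectorized over genes). Parsimony rather than a likelihood model was chosen
because the score needs only a count, the count is root-invariant, and no
rate model is available for a single binary pattern; the event count is a
lower bound on the true number of events, which the simulator makes
checkable (below). Multifurcations are handled natively by the dynamic
program rather than by arbitrary resolution, avoiding tie-break artifacts.
Gains and losses are not distinguished: only the total enters the score.
Genes invariant over the analysis strains have no inferrable events and are
excluded from scoring with a logged count — pan-genome matrices routinely
contain core genes and single-genome clusters that cannot be scored.

## Null distributions

**Permutation test.** The exchangeable unit is the strain, so the null
permutes the vector of per-strain mean phenotypes across strain labels
while the tree and the matrix stay fixed; every gene's score is recomputed
per permutation with $\sigma$ re-derived, and p-values use the add-one rule
$p = (1 + \#\{|S^*| \ge |S|\})/(1+N)$, bounded below by $1/(N+1)$. This is
the minimal exchangeable null at the design's unit; permuting replicates
instead would test a different (and too liberal) hypothesis, because
replicates within a strain share the strain effect.

**Tree-based confirmation scores.** Three statistics probe different
signatures of association, adapted to a continuous phenotype: *terminal*,
the absolute correlation between tip presence and per-strain means
(association at the leaves, ignoring history); *simultaneous*, the
absolute sum over branches of the genotype change (from a minimum-change
ancestral labeling) times the phenotype change (from squared-change
parsimony, i.e. the Brownian-motion ML reconstruction) on the same branch
(co-occurring changes); and *subsequent*, the length-weighted absolute sum
of reconstructed genotype state times phenotype change (phenotype change
while the gene is present). Their null distributions preserve each gene's
observed homoplasy: genotype vectors are simulated by placing exactly
$n_g$ state-change events on branches with probability proportional to
branch length, with a fair-coin root state, and empirical p-values again
use the add-one rule. Null draws are shared across genes with equal
$n_g$, which keeps the cost proportional to the number of distinct event
counts rather than the number of genes.

The original formulation of these three scores targets binary phenotypes;
the continuous-trait adaptations above are this package's own definitions,
kept deliberately simple and documented here rather than claimed to
reproduce any external implementation.

**Multiple testing.** Benjamini–Hochberg q-values are attached to the
permutation p-values as a convenience; the per-gene p-values remain the
primary output.

## Strain-group contrasts

Downstream of the per-gene scan, the package reproduces the standard
contrasts of a mono-association study: a Kruskal–Wallis test of offspring
across strains; a Mann–Whitney test between strain groups defined by joint
presence of a gene set (all-of semantics, e.g. a complete thiamine
biosynthesis pathway), computed on per-strain *medians* with the exact null
when the total number of strains is at most 20; a linear model of offspring
on strain plus $\log_{10}(\mathrm{CFU}+1)$ bacterial load (the load
transform is a package choice — the scale of plate counts spans orders of
magnitude — and is recorded in the model summary); and a supplementation
contrast on *relative offspring* (each non-carrier strain's offspring
divided by the carrier-group mean within the same treatment arm; parity
equals 1), tested with a linear mixed-effects model (REML) with treatment
as fixed effect and strain as random intercept. Degrees of freedom follow
the containment (inner–outer) rule of `nlme::lme`, the smallest defensible
structure matching a "linear mixed effects model" with repeated measures
per strain. Group means always use means for $D_g$ and medians for the
rank tests — the two reductions are deliberately kept distinct and are
computed internally from replicate-level tables, never accepted
pre-aggregated.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. It emulates
the structure of a 17-strain mono-association experiment:

* **Tree**: a supplied newick tree, or a pure-birth tree rescaled to unit
  height so that gain/loss rates act through rate × depth products.
* **Gene content**: each of `n_genes` clusters evolves independently as a
  two-state continuous-time Markov chain (gain rate $a$, loss rate $b$ per
  unit branch length, Bernoulli($\pi_0$) root state). The exact number of
  state changes per gene is recorded, so the parsimony lower bound
  $n_g \le \text{true events}$ is assertable on every fixture.
* **Phenotype**: strain means $\mu_0 + \sum_{\text{causal}} \beta\,x_{gs}
  + \varepsilon_s$ with $\varepsilon_s \sim N(0,\tau^2)$, floored at 0.5;
  replicate offspring counts are negative binomial with that mean and
  dispersion `size` (counts, not normal deviates, because the phenotype is
  a count; large `size` recovers the Poisson limit, which a moment check
  in the tests verifies). A load column and a weight column with no signal
  are included so tables have the shape of a full assay export.

Defaults (`gain_rate = 0.3`, `loss_rate = 2`, `root_prob = 0.1` on a
unit-height tree; `mu0 = 40`, `tau = 6`, `size = 8`, 5–13 replicates per
strain for the 17-strain preset) were chosen to mimic a multi-genus
pan-genome and a fitness assay of a few dozen offspring per female:
roughly a quarter of simulated clusters are singletons, another third are
present in 2–4 strains, and variable genes need about 1.9 events on
average. The causal effect of the `mono_association_config()` preset is 12
offspring (30% of baseline), on the order of a vitamin-supplementation
effect; no effect size in offspring units is available to anchor it more
precisely, so it is documented as a free parameter. The `"auto"` causal
spec designates the variable gene with presence frequency closest to 1/2
— an informative, balanced split like a complete-pathway contrast.

What the generator does **not** emulate: a stable core genome (a single
rate class cannot produce both a singleton-rich cloud and genes retained
everywhere; core genes are invariant and unscorable, so this does not
affect the analysis layer), genomic linkage (genes evolve independently,
whereas real neighboring genes travel together — the test-suite documents
the consequence that identical patterns always get identical scores),
rate heterogeneity across genes, and any real dependence of offspring on
bacterial load. Passing tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to every feature of real
data.

## Numerical choices

* Zero-length branches are replaced by $10^{-8}\times$ tree height for the
  continuous reconstruction only; parsimony counting ignores lengths.
* Ancestral genotype labelings break ties deterministically: absence at
  the root, the parent's state along an edge.
* Rank ordering rounds $|S_g|$ to 12 significant digits before applying
  the lexicographic gene-id tie-break, so that mirror-image patterns
  (mathematically tied scores differing in the last float bit) order
  reproducibly, and empirical p-value comparisons carry a $10^{-9}$
  absolute slack so that p-values are bit-stable under affine phenotype
  rescaling.
* One top-level seed fans out deterministically into per-stage child
  seeds (tree, gene content, phenotypes, permutations, null simulations),
  so each stage is reproducible in isolation.
* Strain means are floored at 0.5 to keep negative-binomial sampling
  defined; every application of the floor is reported.

## Problem sizes

The shipped tests exercise the parsimony oracle on 200 random trees of up
to 8 tips against exhaustive enumeration; type-I calibration at 20
strains × 500 genes × 999 permutations over three seeds; causal-gene
recovery at 20 strains × 2,000 genes × 10 replicates over 100 simulated
datasets; and full-pipeline invariance checks on the 17-strain, 2,000-gene
preset. These sizes were chosen to estimate each property with useful
precision while keeping the default test run quick.

## Known limitations

* With a balanced causal split, $\sigma$ itself grows with the causal
  effect ($\sigma^2 \approx s^2 + \beta^2 p(1-p)$ for null spread $s$ and
  carrier frequency $p$), so the causal score saturates at
  $\sqrt{n_g}/\sqrt{p(1-p)}$ — i.e. $2\sqrt{n_g}$ at $p = 1/2$ — however
  large $\beta$ becomes. Moderate effects (a few null SDs) are
  therefore not guaranteed to out-rank the extreme order statistics of
  thousands of null genes; the permutation and tree-null p-values, not the
  raw rank, are the calibrated quantities.
* The tree is taken as known and fixed; uncertainty in the phylogeny is
  not propagated.
* The tree-null scores condition on the observed $n_g$; genes with very
  high homoplasy get conservative nulls because event placements are
  resampled independently of gene frequency.
* Strain-level covariates other than load are not modeled; the load model
  assumes a common load slope across strains.
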