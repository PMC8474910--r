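# The presence/absence association score, its permutation null, and the
# three tree-aware confirmation scores with simulation-based p-values.

# Comparisons between observed and null statistics use a small absolute
# slack so that empirical p-values are stable under affine rescaling of the
# phenotype (floating-point sums of permuted values can differ in the last
# bit).
P_TOL <- 1e-9

# Rank ordering rounds |score| to 12 significant digits first: genes with
# mirror-image patterns have mathematically equal |score| but can differ in
# the last float bit, and the documented lexicographic tie-break must see
# them as tied.
rank_order <- function(score, gene) {
  order(-signif(abs(score), 12), gene, method = "radix")
}

# Restrict the three sources to their common strain set, drop unscoreable
# genes, and precompute per-strain means. Shared by all association entry
# points.
prepare_association <- function(tree, pa, pheno) {
  val <- validate_inputs(tree, pa, pheno)
  strains <- val$strains
  tree2 <- if (length(strains) < length(tree$tip.label))
    ape::keep.tip(tree, strains) else tree
  pa2 <- pa[val$scoreable_genes, strains, drop = FALSE]
  # pruning can make further genes invariant; re-check on the final set
  rs <- rowSums(pa2)
  keep <- rs > 0L & rs < ncol(pa2)
  pa2 <- pa2[keep, , drop = FALSE]
  if (nrow(pa2) == 0L)
    stop("nothing to test: all genes invariant over the analysis strains")
  pheno2 <- pheno[pheno$strain %in% strains, , drop = FALSE]
  ann <- attr(pa, "annotation")
  list(tree = tree2, pa = pa2, pheno = pheno2,
       means = strain_means(pheno2)[strains],
       annotation = if (!is.null(ann)) ann[rownames(pa2)] else
         stats::setNames(rep("", nrow(pa2)), rownames(pa2)),
       n_invariant = val$n_invariant + sum(!keep))
}

global_sigma <- function(means, pheno, sigma_mode) {
  sigma <- switch(sigma_mode,
    strain_means = stats::sd(means),
    replicates = stats::sd(pheno$offspring)
  )
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate phenotype: global standard deviation is zero")
  sigma
}

# Vectorized group mean difference: presence-group mean minus absence-group
# mean, per gene. `pa` genes x strains, `means` aligned to columns.
group_mean_diff <- function(pa, means) {
  n1 <- rowSums(pa)
  n0 <- ncol(pa) - n1
  drop(pa %*% means) / n1 - drop((1 - pa) %*% means) / n0
}

#' Presence/absence association score for a single gene
#'
#' The score is \eqn{\sqrt{n_g}\, D_g / \sigma}: the difference \eqn{D_g}
#' between the mean phenotype of strains carrying the gene and strains
#' lacking it, in units of the global phenotype standard deviation
#' \eqn{\sigma}, weighted by the square root of the number of gain/loss
#' events \eqn{n_g} the pattern requires on the phylogeny. The score is
#' signed: positive when carriers have the higher phenotype. Its magnitude
#' is invariant under positive affine transforms of the phenotype.
#'
#' @param strain_means named numeric vector of per-strain mean phenotype.
#' @param presence named 0/1 vector over the same strains.
#' @param n_g parsimony gain/loss count for the pattern (>= 1).
#' @param sigma global phenotype standard deviation (> 0).
#' @return the signed association score.
#' @examples
#' m <- c(A = 10, B = 10, C = 20, D = 20)
#' p <- c(A = 0, B = 0, C = 1, D = 1)
#' pa_score(m, p, n_g = 1, sigma = sd(m))  # 1.7321
#' @export
pa_score <- function(strain_means, presence, n_g, sigma) {
  stopifnot(length(strain_means) == length(presence))
  presence <- presence[names(strain_means)]
  if (any(is.na(presence))) stop("presence vector must cover every strain")
  if (all(presence == 1) || all(presence == 0))
    stop("both presence groups must be non-empty")
  if (sigma <= 0) stop("degenerate phenotype: sigma must be > 0")
  if (n_g < 1) stop("n_g must be >= 1 for a variable gene")
  d <- mean(strain_means[presence == 1]) - mean(strain_means[presence == 0])
  sqrt(n_g) * d / sigma
}

#' Score every gene in a presence/absence matrix
#'
#' Computes per-strain mean phenotypes, the global \eqn{\sigma}, parsimony
#' event counts and the association score for every scoreable gene (genes
#' invariant over the analysis strains are excluded, with their count
#' recorded in the attributes). Results are ordered by decreasing absolute
#' score, ties broken by gene id.
#'
#' @param tree strain phylogeny ([ape::phylo]).
#' @param pa presence/absence matrix from [read_pa_matrix()] or
#'   [simulate_presence_absence()].
#' @param pheno replicate-level phenotype table.
#' @param sigma_mode how the global standard deviation is computed:
#'   `"strain_means"` (default) is the sample SD of per-strain mean
#'   offspring over the analysis strains; `"replicates"` is the SD over all
#'   replicate-level values.
#' @return data.frame with columns `gene`, `annotation`, `D_g`, `sigma`,
#'   `n_g`, `pa_score`; attributes `sigma`, `sigma_mode`, `n_invariant`.
#' @export
score_genes <- function(tree, pa, pheno,
                        sigma_mode = c("strain_means", "replicates")) {
  sigma_mode <- match.arg(sigma_mode)
  prep <- prepare_association(tree, pa, pheno)
  sigma <- global_sigma(prep$means, prep$pheno, sigma_mode)
  ev <- count_events(prep$tree, prep$pa)
  d <- group_mean_diff(prep$pa, prep$means)
  res <- data.frame(
    gene = rownames(prep$pa),
    annotation = unname(prep$annotation),
    D_g = unname(d),
    sigma = sigma,
    n_g = ev$n_g,
    pa_score = sqrt(ev$n_g) * unname(d) / sigma,
    stringsAsFactors = FALSE
  )
  res <- res[rank_order(res$pa_score, res$gene), ]
  rownames(res) <- NULL
  attr(res, "sigma") <- sigma
  attr(res, "sigma_mode") <- sigma_mode
  attr(res, "n_invariant") <- prep$n_invariant
  res
}

#' Permutation p-values for the association scores
#'
#' The exchangeable unit of the design is the strain (phenotypes are
#' measured on hosts mono-associated with one strain), so the null permutes
#' the vector of per-strain mean phenotypes across strain labels while tree
#' and matrix stay fixed. All gene scores are recomputed in every
#' permutation, with \eqn{\sigma} re-derived from the permuted assignment,
#' and the per-gene empirical p-value uses the add-one rule
#' \eqn{p = (1 + \#\{|s^*| \ge |s|\}) / (1 + N)}, so \eqn{p \ge 1/(N+1)}.
#'
#' @inheritParams score_genes
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return named numeric vector of p-values (names = gene ids).
#' @export
permutation_pvalues <- function(tree, pa, pheno, n_perm = 999, seed = 1,
                                sigma_mode = c("strain_means", "replicates")) {
  sigma_mode <- match.arg(sigma_mode)
  if (n_perm < 99) stop("n_perm must be at least 99")
  prep <- prepare_association(tree, pa, pheno)
  means <- prep$means
  sigma <- global_sigma(means, prep$pheno, sigma_mode)
  ev <- count_events(prep$tree, prep$pa)
  w <- sqrt(ev$n_g)
  obs <- abs(w * group_mean_diff(prep$pa, means) / sigma)
  s <- length(means)
  perm <- with_seed(child_seed(seed, "permutation"),
                    replicate(n_perm, sample.int(s)))
  M <- matrix(means[perm], nrow = s)          # strains x n_perm
  n1 <- rowSums(prep$pa)
  n0 <- s - n1
  D <- (prep$pa %*% M) / n1 - ((1 - prep$pa) %*% M) / n0
  # permuting means across labels leaves their multiset, hence sigma,
  # unchanged under either definition; re-derive anyway for clarity
  sig_perm <- if (sigma_mode == "strain_means") apply(M, 2, stats::sd)
              else rep(sigma, n_perm)
  scores <- abs(sweep(D, 2, sig_perm, "/") * w)
  exceed <- rowSums(scores >= obs - P_TOL)
  stats::setNames((1 + exceed) / (1 + n_perm), rownames(prep$pa))
}

# --- tree-aware confirmation scores -------------------------------------

# The three statistics, given per-branch genotype information and the
# reconstructed phenotype changes. All are absolute values; larger = more
# association.
#   terminal:     |cor(tip presence, tip strain means)|
#   simultaneous: |sum_b dx_b * dy_b|, dx_b in {-1,0,+1}
#   subsequent:   |sum_b rel_len_b * mean(x at branch ends) * dy_b|
tree_stats <- function(tip_states, x_parent, x_child, dy, rel_len, means) {
  tt <- ncol(tip_states)
  mc <- means - mean(means)
  sdm <- stats::sd(means)
  sdx <- apply(tip_states, 1, stats::sd)
  terminal <- abs(tip_states %*% mc) / ((tt - 1) * sdx * sdm)
  terminal[!is.finite(terminal)] <- 0
  dx <- x_child - x_parent
  simultaneous <- abs(dx %*% dy)
  xbar <- (x_child + x_parent) / 2
  subsequent <- abs(sweep(xbar, 2, rel_len, "*") %*% dy)
  cbind(terminal = drop(terminal), simultaneous = drop(simultaneous),
        subsequent = drop(subsequent))
}

#' Tree-based null p-values for the three confirmation scores
#'
#' For each gene three statistics are computed from the joint ancestral
#' reconstruction of genotype (minimum-change parsimony labeling) and
#' phenotype (squared-change parsimony): `terminal`, the absolute
#' correlation between tip presence and per-strain mean phenotype;
#' `simultaneous`, the absolute sum over branches of the genotype change
#' times the phenotype change on the same branch; and `subsequent`, the
#' absolute sum of reconstructed genotype state (mean of branch endpoints)
#' times phenotype change, weighted by relative branch length. The null
#' distribution for a gene preserves its observed homoplasy: `n_sims`
#' genotype vectors are simulated by placing exactly \eqn{n_g} state-change
#' events on branches with probability proportional to branch length (root
#' state fair Bernoulli), and empirical p-values use the add-one rule.
#'
#' @inheritParams score_genes
#' @param n_sims null genotype simulations per distinct \eqn{n_g} (>= 99).
#' @param seed integer seed for the null-simulation stream.
#' @return data.frame with columns `gene`, `terminal_p`, `simultaneous_p`,
#'   `subsequent_p`.
#' @export
tree_null_pvalues <- function(tree, pa, pheno, n_sims = 999, seed = 1) {
  if (n_sims < 99) stop("n_sims must be at least 99")
  prep <- prepare_association(tree, pa, pheno)
  means <- prep$means
  anc <- ancestral_states_parsimony(prep$tree, prep$pa)
  tr <- anc$tree                       # postorder; edges fixed below
  ntip <- length(tr$tip.label)
  e <- tr$edge
  len <- tr$edge.length
  if (is.null(len)) len <- rep(1, nrow(e))
  len_pos <- pmax(len, 1e-8 * max(ape::node.depth.edgelength(tr), 1e-12))
  rel_len <- len_pos / sum(len_pos)
  apc <- ancestral_phenotype_changes(tr, means)
  dy <- apc$dy
  m_aligned <- means[tr$tip.label]

  obs <- tree_stats(
    tip_states = prep$pa[, tr$tip.label, drop = FALSE],
    x_parent = anc$states[, e[, 1L], drop = FALSE],
    x_child = anc$states[, e[, 2L], drop = FALSE],
    dy = dy, rel_len = rel_len, means = m_aligned
  )

  ev <- count_events(tr, prep$pa)
  n_g <- ev$n_g
  exceed <- matrix(0L, nrow(prep$pa), 3L)
  rng_seed <- child_seed(seed, "tree_null")
  for (k in sort(unique(n_g))) {
    null_stats <- with_seed(rng_seed + k, {
      counts <- stats::rmultinom(n_sims, k, prob = len_pos)  # edges x sims
      parity <- counts %% 2L
      x <- matrix(0L, ntip + tr$Nnode, n_sims)
      x[ntip + 1L, ] <- stats::rbinom(n_sims, 1L, 0.5)
      for (i in rev(seq_len(nrow(e))))    # preorder
        x[e[i, 2L], ] <- (x[e[i, 1L], ] + parity[i, ]) %% 2L
      tree_stats(
        tip_states = t(x[seq_len(ntip), , drop = FALSE]),
        x_parent = t(x[e[, 1L], , drop = FALSE]),
        x_child = t(x[e[, 2L], , drop = FALSE]),
        dy = dy, rel_len = rel_len, means = m_aligned
      )
    })
    rows <- which(n_g == k)
    for (j in 1:3)
      exceed[rows, j] <- vapply(
        obs[rows, j], function(o) sum(null_stats[, j] >= o - P_TOL), 0
      )
  }
  p <- (1 + exceed) / (1 + n_sims)
  out <- data.frame(
    gene = rownames(prep$pa),
    terminal_p = p[, 1L], simultaneous_p = p[, 2L], subsequent_p = p[, 3L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  rownames(obs) <- rownames(prep$pa)
  attr(out, "observed") <- obs
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (a thin wrapper around [stats::p.adjust()] kept for a stable interface).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in the same order.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Run the full pan-genome association pipeline
#'
#' Validates the inputs, scores every gene, attaches permutation p-values,
#' the three tree-based confirmation p-values, and the FDR-adjusted q-value
#' of the permutation p. One top-level seed fans out into independent
#' per-stage seeds, so each stage is reproducible on its own.
#'
#' @inheritParams score_genes
#' @param n_perm permutations for [permutation_pvalues()].
#' @param n_null_sims simulations for [tree_null_pvalues()].
#' @param seed top-level integer seed.
#' @return data.frame ordered by decreasing `|pa_score|` with columns
#'   `gene`, `annotation`, `D_g`, `sigma`, `n_g`, `pa_score`, `perm_p`,
#'   `terminal_p`, `simultaneous_p`, `subsequent_p`, `q`.
#' @export
pan_gwas <- function(tree, pa, pheno, n_perm = 999, n_null_sims = 999,
                     sigma_mode = c("strain_means", "replicates"), seed = 1) {
  sigma_mode <- match.arg(sigma_mode)
  res <- score_genes(tree, pa, pheno, sigma_mode)
  perm <- permutation_pvalues(tree, pa, pheno, n_perm, seed, sigma_mode)
  res$perm_p <- unname(perm[res$gene])
  tn <- tree_null_pvalues(tree, pa, pheno, n_null_sims, seed)
  res <- merge(res, tn, by = "gene", sort = FALSE)
  res$q <- fdr_adjust(res$perm_p)
  res <- res[rank_order(res$pa_score, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Write association results as TSV
#'
#' @param results data.frame from [pan_gwas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
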