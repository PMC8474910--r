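# Synthetic strain trees, gene presence/absence matrices evolved by a
# two-state gain/loss process, and replicate-level count phenotypes with
# designated causal genes. The generator reproduces the statistical
# structure the association machinery assumes, so every downstream stage is
# testable without external data.

#' Configuration for the synthetic-data generator
#'
#' Gene content evolves independently per gene as a two-state
#' continuous-time Markov chain along the tree: absent genes are gained at
#' rate `gain_rate` and present genes lost at rate `loss_rate` (events per
#' unit branch length); the root state is Bernoulli(`root_prob`). Strain
#' mean phenotypes are `mu0` plus the summed effects of the causal genes a
#' strain carries plus Normal(0, `tau`^2) strain noise, floored at 0.5 so
#' that count sampling stays defined; replicate offspring counts are
#' negative binomial with that mean and dispersion `size` (large `size`
#' approaches the Poisson limit).
#'
#' @param n_strains number of strains (ignored if `tree` supplied).
#' @param tree optional [ape::phylo] to use instead of a simulated one;
#'   `NULL` simulates a pure-birth tree rescaled to unit height, so rates
#'   act through the products rate x depth.
#' @param gain_rate,loss_rate gain (0 to 1) and loss (1 to 0) rates.
#' @param root_prob probability the root carries a gene.
#' @param n_genes number of independently evolving gene clusters.
#' @param causal_genes `"auto"` to pick one informative causal gene at
#'   generation time (presence frequency closest to 1/2, ties to the lowest
#'   index), or an integer vector of gene indices.
#' @param causal_beta effect, in offspring units, each causal gene adds to
#'   the mean of strains carrying it (recycled to `length(causal_genes)`).
#' @param mu0 baseline mean offspring per replicate (> 0).
#' @param tau SD of strain-level noise on the mean (offspring units).
#' @param size negative-binomial dispersion of replicate counts (> 0).
#' @param replicates replicates per strain: a single integer, or a length-2
#'   range from which each strain's replicate number is drawn uniformly.
#' @param seed top-level integer seed; fanned out to independent per-stage
#'   seeds (tree, presence/absence, phenotypes).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_strains = 17, tree = NULL,
                       gain_rate = 0.3, loss_rate = 2, root_prob = 0.1,
                       n_genes = 2000,
                       causal_genes = "auto", causal_beta = 12,
                       mu0 = 40, tau = 6, size = 8,
                       replicates = c(5, 13), seed = 1) {
  stopifnot(gain_rate >= 0, loss_rate >= 0,
            root_prob >= 0, root_prob <= 1,
            n_genes >= 1, mu0 > 0, tau >= 0, size > 0,
            length(replicates) %in% 1:2, all(replicates >= 1))
  if (!is.null(tree)) n_strains <- length(tree$tip.label)
  if (n_strains < 2) stop("need at least 2 strains")
  if (!identical(causal_genes, "auto")) {
    causal_genes <- as.integer(causal_genes)
    if (any(causal_genes < 1 | causal_genes > n_genes))
      stop("causal gene index out of range")
  }
  cfg <- list(
    n_strains = n_strains, tree = tree,
    gain_rate = gain_rate, loss_rate = loss_rate, root_prob = root_prob,
    n_genes = n_genes,
    causal_genes = causal_genes,
    causal_beta = rep_len(causal_beta,
                          if (identical(causal_genes, "auto")) 1L
                          else length(causal_genes)),
    mu0 = mu0, tau = tau, size = size,
    replicates = as.integer(replicates), seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Mono-association experiment preset of the generator
#'
#' The study design this generator emulates: 17 mono-associated strains,
#' a pan-genome of a few thousand clusters, 5-13 replicate vials per
#' strain, and offspring counts of a few dozen per female. One causal gene
#' carries an effect of 12 offspring (30% of baseline), on the order of the
#' thiamine-supplementation lift seen in such assays.
#'
#' @param seed top-level integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
mono_association_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_strains = 17, n_genes = 2000, replicates = c(5, 13), seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

#' Read a simulator configuration from YAML
#'
#' The YAML keys mirror the arguments of [sim_config()] field for field;
#' unknown keys are an error. A `tree` key, if present, is a path to a
#' newick file.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$tree)) cfg$tree <- read_tree(cfg$tree)
  do.call(sim_config, cfg)
}

#' Simulate a strain tree
#'
#' Pure-birth (Yule) tree rescaled to unit height, so that gain/loss rates
#' interact with topology only through the rate x depth products.
#'
#' @param n_strains number of tips.
#' @param seed integer seed.
#' @return [ape::phylo] with tip labels `s01, s02, ...` and height 1.
#' @export
simulate_strain_tree <- function(n_strains, seed = 1) {
  tree <- with_seed(seed, ape::rphylo(n_strains, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("s%02d", seq_len(n_strains))
  tree
}

# CTMC transition along one branch for all genes at once, tracking the
# exact number of flips. state: 0/1 integer vector; t: branch length.
evolve_branch <- function(state, t, gain_rate, loss_rate) {
  events <- integer(length(state))
  remaining <- rep(t, length(state))
  active <- seq_along(state)
  repeat {
    rate <- ifelse(state[active] == 1L, loss_rate, gain_rate)
    live <- rate > 0
    if (!any(live)) break
    active <- active[live]
    wait <- stats::rexp(length(active), rate[live])
    flip <- wait < remaining[active]
    if (!any(flip)) break
    hit <- active[flip]
    state[hit] <- 1L - state[hit]
    events[hit] <- events[hit] + 1L
    remaining[hit] <- remaining[hit] - wait[flip]
    active <- hit
  }
  list(state = state, events = events)
}

#' Evolve gene presence/absence down a tree
#'
#' Each gene evolves independently as the two-state gain/loss chain of
#' [sim_config()]. The exact number of state-change events per gene is
#' recorded in `attr(, "true_events")` — parsimony counts computed
#' downstream are a lower bound on these, which the test-suite asserts on
#' every fixture.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param cfg a `sim_config` (its `seed` fans out to the presence stage).
#' @return integer presence/absence matrix (genes x strains) with
#'   `attr(, "true_events")`: named integer vector of simulated event
#'   counts per gene.
#' @export
simulate_presence_absence <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(g))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  e <- tr$edge
  len <- tr$edge.length
  if (is.null(len)) stop("tree must have branch lengths")
  with_seed(child_seed(cfg$seed, "presence"), {
    states <- matrix(NA_integer_, g, nnode)
    states[, ntip + 1L] <- stats::rbinom(g, 1L, cfg$root_prob)
    events <- integer(g)
    for (i in rev(seq_len(nrow(e)))) {    # preorder: parent before child
      res <- evolve_branch(states[, e[i, 1L]], len[i],
                           cfg$gain_rate, cfg$loss_rate)
      states[, e[i, 2L]] <- res$state
      events <- events + res$events
    }
    pa <- states[, seq_len(ntip), drop = FALSE]
    dimnames(pa) <- list(genes, tr$tip.label)
    attr(pa, "true_events") <- stats::setNames(events, genes)
    pa
  })
}

#' Pick an informative causal gene
#'
#' The designated causal gene of the `"auto"` causal spec: the variable
#' gene whose presence frequency is closest to 1/2 (ties to the lowest
#' index) — a balanced carrier/non-carrier split like the thiamine pathway
#' contrast the design emulates.
#'
#' @param pa presence/absence matrix (genes x strains).
#' @return integer row index of the chosen gene.
#' @export
pick_causal_gene <- function(pa) {
  freq <- rowMeans(pa)
  variable <- freq > 0 & freq < 1
  if (!any(variable)) stop("no variable gene to designate as causal")
  idx <- which(variable)
  idx[which.min(abs(freq[idx] - 0.5))]
}

#' Expected SD of strain mean phenotypes under the null
#'
#' Closed form for the between-strain SD of observed strain means when no
#' causal gene acts: strain noise `tau` plus the sampling noise of the mean
#' of `r` negative-binomial replicates,
#' \eqn{\sqrt{\tau^2 + (\mu_0 + \mu_0^2/k)/r}} with `r` the mean replicate
#' number. Used to express effect sizes in units of null strain spread.
#'
#' @param cfg a `sim_config`.
#' @return positive number, in offspring units.
#' @export
null_strain_mean_sd <- function(cfg) {
  r <- mean(cfg$replicates)
  sqrt(cfg$tau^2 + (cfg$mu0 + cfg$mu0^2 / cfg$size) / r)
}

#' Simulate replicate-level phenotypes from gene content
#'
#' Strain means are `mu0` plus the causal effects of carried genes plus
#' Normal(0, tau^2) strain noise, floored at 0.5 (a message reports how
#' often the floor was applied); replicate offspring counts are negative
#' binomial with that mean and size `cfg$size`. An independent log-normal
#' `cfu` load column and a Normal weight-per-fly column are included so the
#' table has the shape of a full fitness-assay export; both are pure noise,
#' carrying no signal about gene content.
#'
#' @param pa presence/absence matrix from [simulate_presence_absence()].
#' @param cfg a `sim_config`; `causal_genes = "auto"` resolves via
#'   [pick_causal_gene()] here.
#' @return replicate-level phenotype data.frame (`strain`, `replicate`,
#'   `offspring`, `cfu`, `weight`) with attributes `causal_genes` (gene
#'   ids), `causal_beta`, and `strain_means` (the latent means used).
#' @export
simulate_phenotypes <- function(pa, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  strains <- colnames(pa)
  causal <- cfg$causal_genes
  if (identical(causal, "auto")) causal <- pick_causal_gene(pa)
  if (any(causal < 1 | causal > nrow(pa)))
    stop("causal gene index out of range")
  beta <- rep_len(cfg$causal_beta, length(causal))
  with_seed(child_seed(cfg$seed, "phenotype"), {
    effect <- drop(crossprod(pa[causal, , drop = FALSE], beta))
    m <- cfg$mu0 + effect + stats::rnorm(length(strains), 0, cfg$tau)
    floored <- m < 0.5
    if (any(floored))
      message(sum(floored), " strain mean(s) floored at 0.5")
    m <- pmax(m, 0.5)
    r <- if (length(cfg$replicates) == 2L)
      sample(cfg$replicates[1L]:cfg$replicates[2L], length(strains),
             replace = TRUE)
    else rep(cfg$replicates, length(strains))
    pheno <- data.frame(
      strain = rep(strains, r),
      replicate = unlist(lapply(r, function(n) sprintf("r%02d", seq_len(n)))),
      offspring = stats::rnbinom(sum(r), mu = rep(m, r), size = cfg$size),
      cfu = round(stats::rlnorm(sum(r), meanlog = log(1e4), sdlog = 1)),
      weight = round(stats::rnorm(sum(r), 1.0, 0.05), 3),
      stringsAsFactors = FALSE
    )
    attr(pheno, "causal_genes") <- rownames(pa)[causal]
    attr(pheno, "causal_beta") <- beta
    attr(pheno, "strain_means") <- stats::setNames(m, strains)
    pheno
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Simulates (or reuses) the tree, evolves the presence/absence matrix,
#' draws phenotypes, and writes `tree.nwk`, `pa_matrix.tsv`,
#' `phenotypes.tsv` and `truth.tsv` (per gene: causal flag, effect, true
#' simulated event count) into `outdir`. Identical configurations produce
#' byte-identical files.
#'
#' @param cfg a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory `tree`, `pa`, `pheno`,
#'   `truth` and the file paths.
#' @export
make_fixture <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tree <- if (is.null(cfg$tree))
    simulate_strain_tree(cfg$n_strains, child_seed(cfg$seed, "tree"))
  else cfg$tree
  pa <- simulate_presence_absence(tree, cfg)
  pheno <- simulate_phenotypes(pa, cfg)
  causal_ids <- attr(pheno, "causal_genes")
  truth <- data.frame(
    gene = rownames(pa),
    causal = rownames(pa) %in% causal_ids,
    beta = 0,
    true_events = unname(attr(pa, "true_events")),
    stringsAsFactors = FALSE
  )
  truth$beta[match(causal_ids, truth$gene)] <- attr(pheno, "causal_beta")
  paths <- list(
    tree = file.path(outdir, "tree.nwk"),
    pa = file.path(outdir, "pa_matrix.tsv"),
    pheno = file.path(outdir, "phenotypes.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_tree(tree, paths$tree)
  write_pa_matrix(pa, paths$pa)
  write_phenotypes(pheno, paths$pheno)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(tree = tree, pa = pa, pheno = pheno, truth = truth,
                 paths = paths))
}
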