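# Independent oracles and small in-code fixtures shared across test files.

# Brute-force parsimony count: enumerate all 2^(internal nodes) labelings
# and take the minimum number of changed edges. Independent of the Sankoff
# dynamic program it checks.
brute_force_count <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  e <- tree$edge
  states <- integer(ntip + nint)
  states[seq_len(ntip)] <- as.integer(tip_states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^nint - 1L)) {
    states[(ntip + 1L):(ntip + nint)] <-
      as.integer(intToBits(code))[seq_len(nint)]
    best <- min(best, sum(states[e[, 1L]] != states[e[, 2L]]))
  }
  best
}

# A random tree with n tips labelled t1..tn (topology only relevant for
# parsimony checks; unit branch lengths).
random_small_tree <- function(n) {
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("t%d", seq_len(n))
  tr
}

# The 4-strain toy used throughout: balanced tree, clade-concordant gene,
# strain means 10,10,20,20.
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
toy_means <- c(A = 10, B = 10, C = 20, D = 20)

# Replicate-level phenotype table with given per-strain values repeated
# exactly (so strain means equal the given values).
constant_pheno <- function(means, r = 3) {
  data.frame(
    strain = rep(names(means), each = r),
    replicate = rep(sprintf("r%d", seq_len(r)), length(means)),
    offspring = rep(as.integer(means), each = r),
    stringsAsFactors = FALSE
  )
}

# Small presence/absence matrix builder.
pa_mat <- function(..., strains) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), strains)
  storage.mode(m) <- "integer"
  m
}
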