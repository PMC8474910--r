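# Parsimony counting of gene gain/loss events and continuous ancestral
# reconstruction of the phenotype along branches. Both operate on arbitrary
# (possibly multifurcating) trees; event counts are computed by a unit-cost
# Sankoff dynamic program vectorized over genes.

# Sankoff unit-cost DP over all genes at once.
# states: genes x strains binary matrix (colnames = tip labels).
# Returns list(cost0, cost1): genes x (Ntip + Nnode) matrices of minimal
# change counts for the subtree below each node given its state.
BIG <- 1e9

sankoff_costs <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  g <- nrow(states)
  states <- states[, tree$tip.label, drop = FALSE]
  cost0 <- matrix(0, g, nnode)
  cost1 <- matrix(0, g, nnode)
  cost0[, seq_len(ntip)] <- ifelse(states == 0L, 0, BIG)
  cost1[, seq_len(ntip)] <- ifelse(states == 1L, 0, BIG)
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    cost0[, p] <- cost0[, p] + pmin(cost0[, ch], cost1[, ch] + 1)
    cost1[, p] <- cost1[, p] + pmin(cost1[, ch], cost0[, ch] + 1)
  }
  list(cost0 = cost0, cost1 = cost1, tree = tree)
}

#' Minimum number of binary state changes on a tree (Fitch/Sankoff parsimony)
#'
#' Counts the minimum number of gain/loss events needed to explain a binary
#' tip pattern on the strain tree, minimising over all internal labelings.
#' Multifurcations are handled natively by the unit-cost Sankoff dynamic
#' program (no arbitrary resolution), and the count is independent of root
#' placement. Gains and losses are not distinguished: only the total event
#' count enters the association score.
#'
#' @param tree [ape::phylo]; polytomies and zero-length branches allowed.
#' @param tip_states named vector of 0/1 states, names covering every tip.
#' @return non-negative integer: the parsimony event count.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fitch_count(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' fitch_count(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2
#' @export
fitch_count <- function(tree, tip_states) {
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stop("missing tip state(s) for: ", paste(missing, collapse = ", "))
  if (!all(tip_states[tree$tip.label] %in% c(0L, 1L)))
    stop("tip states must be 0/1")
  m <- matrix(as.integer(tip_states[tree$tip.label]), nrow = 1,
              dimnames = list("g", tree$tip.label))
  sc <- sankoff_costs(tree, m)
  root <- length(tree$tip.label) + 1L
  as.integer(min(sc$cost0[1L, root], sc$cost1[1L, root]))
}

#' Parsimony event counts for every gene in a presence/absence matrix
#'
#' Applies the unit-cost parsimony count of [fitch_count()] to every row of
#' the matrix in one vectorized dynamic program. Genes invariant over the
#' tree's strains (all 0 or all 1) have no inferrable events and are flagged;
#' their `n_g` is reported as 0.
#'
#' @param tree [ape::phylo] over the analysis strains.
#' @param pa presence/absence matrix (genes x strains) whose column names
#'   cover every tip of `tree`; extra columns are ignored.
#' @return data.frame with columns `gene`, `n_g` (integer) and `invariant`
#'   (logical).
#' @export
count_events <- function(tree, pa) {
  missing <- setdiff(tree$tip.label, colnames(pa))
  if (length(missing))
    stop("matrix lacks strain column(s): ", paste(missing, collapse = ", "))
  m <- pa[, tree$tip.label, drop = FALSE]
  sc <- sankoff_costs(tree, m)
  root <- length(tree$tip.label) + 1L
  n_g <- as.integer(pmin(sc$cost0[, root], sc$cost1[, root]))
  rs <- rowSums(m)
  data.frame(
    gene = rownames(pa),
    n_g = n_g,
    invariant = rs == 0L | rs == ncol(m),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# One minimum-change internal labeling per gene, by Sankoff traceback.
# Ties at the root prefer absence (state 0); ties along an edge prefer the
# parent's state, so labelings are deterministic. Returns genes x nodes
# 0/1 matrix together with the postorder tree used.
ancestral_states_parsimony <- function(tree, states) {
  sc <- sankoff_costs(tree, states)
  tree <- sc$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  g <- nrow(states)
  x <- matrix(0L, g, ntip + tree$Nnode)
  x[, root] <- as.integer(sc$cost1[, root] < sc$cost0[, root])
  e <- tree$edge
  for (i in rev(seq_len(nrow(e)))) {   # preorder
    p <- e[i, 1L]; ch <- e[i, 2L]
    xp <- x[, p]
    keep <- ifelse(xp == 1L, sc$cost1[, ch], sc$cost0[, ch])
    flip <- ifelse(xp == 1L, sc$cost0[, ch], sc$cost1[, ch]) + 1
    x[, ch] <- ifelse(keep <= flip, xp, 1L - xp)
  }
  list(states = x, tree = tree)
}

#' Reconstruct phenotype changes along branches
#'
#' Assigns ancestral values to internal nodes by squared-change parsimony:
#' the internal values minimise \eqn{\sum_b (\Delta y_b)^2 / \ell_b} over
#' branches \eqn{b} with lengths \eqn{\ell_b} — the maximum-likelihood
#' reconstruction under Brownian motion on a fixed tree. Zero-length (or
#' absent) branch lengths are replaced by \eqn{10^{-8}} times the tree
#' height for this reconstruction only.
#'
#' @param tree [ape::phylo] with at least 2 tips.
#' @param strain_values named numeric vector of tip values (e.g. per-strain
#'   mean offspring), names covering every tip.
#' @return data.frame with one row per branch: `parent`, `child` (node
#'   indices in `ape` numbering), `length` (the possibly epsilon-adjusted
#'   length used), and `dy` (child value minus parent value). Node values
#'   are attached as `attr(, "node_values")` (tips first, then internals).
#' @export
ancestral_phenotype_changes <- function(tree, strain_values) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  missing <- setdiff(tree$tip.label, names(strain_values))
  if (length(missing))
    stop("missing phenotype value(s) for: ", paste(missing, collapse = ", "))
  e <- tree$edge
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, nrow(e))
  depth <- max(ape::node.depth.edgelength(tree), 1e-12)
  eps <- 1e-8 * depth
  len[len <= 0] <- eps
  nnode <- ntip + tree$Nnode
  y <- numeric(nnode)
  y[seq_len(ntip)] <- strain_values[tree$tip.label]
  internal <- (ntip + 1L):nnode
  idx <- match(seq_len(nnode), internal)   # node -> row in linear system
  A <- matrix(0, length(internal), length(internal))
  b <- numeric(length(internal))
  w <- 1 / len
  for (i in seq_len(nrow(e))) {
    p <- idx[e[i, 1L]]; ch <- e[i, 2L]; wi <- w[i]
    A[p, p] <- A[p, p] + wi
    if (ch <= ntip) {
      b[p] <- b[p] + wi * y[ch]
    } else {
      c2 <- idx[ch]
      A[c2, c2] <- A[c2, c2] + wi
      A[p, c2] <- A[p, c2] - wi
      A[c2, p] <- A[c2, p] - wi
    }
  }
  y[internal] <- solve(A, b)
  out <- data.frame(
    parent = e[, 1L], child = e[, 2L], length = len,
    dy = y[e[, 2L]] - y[e[, 1L]]
  )
  attr(out, "node_values") <- y
  out
}
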