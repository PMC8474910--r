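# Internal helpers shared across modules.

# Deterministic fan-out of one user-facing seed into per-stage child seeds,
# so that e.g. the permutation stage is reproducible independently of how
# many random draws earlier stages consumed. Keeps everything < 2^31.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stages <- c(
    tree = 1L, presence = 2L, phenotype = 3L, permutation = 4L,
    tree_null = 5L, fixture = 6L
  )
  k <- stages[[stage]]
  as.integer((abs(seed) * 48271 + 1009 * k) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Per-strain summary of replicate-level phenotypes.
strain_summary <- function(pheno, value = "offspring", fun = mean) {
  stopifnot(is.data.frame(pheno), value %in% names(pheno))
  v <- tapply(pheno[[value]], pheno$strain, fun)
  # tapply on a factor column keeps unused levels; drop NAs from those
  v[!is.na(v)]
}

#' Per-strain mean and median phenotype
#'
#' Replicate-level phenotype tables are always reduced inside the package:
#' means feed the association score \eqn{D_g}, medians feed the rank-based
#' group contrasts. Both reductions are exposed so that reports stay
#' auditable.
#'
#' @param pheno replicate-level phenotype table (see
#'   \code{\link{read_phenotypes}}).
#' @param value column to summarise (default \code{"offspring"}).
#' @return named numeric vector, one entry per strain.
#' @export
strain_means <- function(pheno, value = "offspring") {
  strain_summary(pheno, value, mean)
}

#' @rdname strain_means
#' @export
strain_medians <- function(pheno, value = "offspring") {
  strain_summary(pheno, value, stats::median)
}
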