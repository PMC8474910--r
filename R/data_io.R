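# Reading, writing and cross-validating the three input sources:
# strain phylogeny (newick), gene presence/absence matrix (Roary-style CSV
# or plain binary TSV) and replicate-level phenotype table (TSV).

#' Read a strain phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' association machinery relies on: unique tip labels and non-negative branch
#' lengths. Polytomies, zero-length branches and internal node labels are all
#' retained as-is; tip labels are stripped of surrounding whitespace only.
#'
#' @param path path to a newick file containing a single tree.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  tree
}

#' Write a strain phylogeny to newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a gene presence/absence matrix
#'
#' Two dialects are supported. `binary_tsv` is a plain tab-separated table
#' with gene ids in the first column, one column per strain, and literal 0/1
#' cells. `roary_csv` is the pan-genome tool convention: a CSV whose first
#' two columns are `Gene` and `Annotation` followed by one column per strain,
#' each cell holding the locus tag(s) of the gene in that strain (possibly
#' several, semicolon-separated) or being empty. Roary cells are binarized:
#' any non-empty cell, including multi-copy entries, becomes 1.
#'
#' @param path input file.
#' @param dialect `"roary_csv"`, `"binary_tsv"`, or `"auto"` to sniff from
#'   the header (a first line starting with `Gene,` or
#'   `"Gene","Annotation"` is taken as Roary).
#' @return integer matrix, genes in rows (rownames = gene ids), strains in
#'   columns (colnames = strain ids), cells in \{0, 1\}. For the Roary
#'   dialect the original `Annotation` column is kept in
#'   `attr(, "annotation")`, a character vector named by gene id.
#' @export
read_pa_matrix <- function(path, dialect = c("auto", "roary_csv", "binary_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("presence/absence file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("^\"?Gene\"?,", header)) "roary_csv" else "binary_tsv"
  }
  if (dialect == "roary_csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (!all(c("Gene", "Annotation") %in% names(df)[1:2]))
      stop("Roary dialect requires leading columns 'Gene' and 'Annotation'")
    genes <- trimws(df$Gene)
    if (anyDuplicated(genes))
      stop("duplicate gene ids: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    strain_cols <- setdiff(names(df), c("Gene", "Annotation"))
    if (length(strain_cols) == 0L) stop("no strain columns found")
    m <- vapply(df[strain_cols],
                function(col) as.integer(nzchar(trimws(col))),
                integer(nrow(df)))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(genes, trimws(strain_cols)))
    ann <- stats::setNames(df$Annotation, genes)
    attr(m, "annotation") <- ann
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  genes <- trimws(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- matrix(!(trimws(vals) %in% c("0", "1")), nrow = nrow(vals))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell in binary_tsv at gene '%s', strain '%s': '%s'",
                 genes[idx[1L]], colnames(vals)[idx[2L]], vals[idx[1L], idx[2L]]))
  }
  m <- matrix(as.integer(trimws(vals)), nrow = nrow(df),
              dimnames = list(genes, trimws(colnames(vals))))
  m
}

#' Write a presence/absence matrix as binary TSV
#'
#' Inverse of [read_pa_matrix()] for the `binary_tsv` dialect; round-trips
#' gene ids, strain ids and cell values exactly.
#'
#' @param pa integer presence/absence matrix (genes x strains).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pa_matrix <- function(pa, path) {
  stopifnot(is.matrix(pa), all(pa %in% c(0L, 1L)))
  df <- data.frame(gene = rownames(pa), pa, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate-level phenotype table
#'
#' Tab-separated table with header columns `strain`, `replicate`,
#' `offspring` and optionally `cfu` (bacterial load per fly), `weight`
#' (weight per fly) and `treatment` (free label, e.g. thiamine +/-).
#' Offspring counts must be non-negative integers; the table is kept at
#' replicate level — per-strain means and medians are always computed
#' internally so that the dispersion entering \eqn{\sigma} stays auditable.
#'
#' @param path input TSV.
#' @return data.frame with at least columns `strain` (character),
#'   `replicate` (character) and `offspring` (integer).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("strain", "replicate", "offspring")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phenotype table lacks required column(s): ",
         paste(missing, collapse = ", "))
  df$strain <- trimws(as.character(df$strain))
  df$replicate <- as.character(df$replicate)
  off <- df$offspring
  if (any(is.na(off)) || any(off < 0) || any(off != round(off)))
    stop("offspring counts must be non-negative integers")
  df$offspring <- as.integer(round(off))
  if ("cfu" %in% names(df) && any(df$cfu < 0, na.rm = TRUE))
    stop("cfu values must be non-negative")
  df
}

#' Write a replicate-level phenotype table
#'
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate tree, presence/absence matrix and phenotype table
#'
#' Strain ids are matched by exact string comparison after whitespace
#' stripping (already applied at load time); no fuzzy matching is attempted,
#' since a silently mismatched strain corrupts every group mean downstream.
#' Association runs use the intersection of the three strain sets. Genes
#' that are invariant (all 0 or all 1) over the intersection cannot be
#' scored and are reported as a count, not an error — pan-genome matrices
#' routinely contain core genes and single-genome clusters.
#'
#' @param tree [ape::phylo] strain phylogeny.
#' @param pa presence/absence matrix from [read_pa_matrix()].
#' @param pheno phenotype table from [read_phenotypes()].
#' @return object of class `pan_validation`: a list with `strains`
#'   (intersection, in tree order), `missing` (list of strains absent from
#'   each source), `n_invariant`, `scoreable_genes` (character vector).
#' @export
validate_inputs <- function(tree, pa, pheno) {
  s_tree <- tree$tip.label
  s_pa <- colnames(pa)
  s_ph <- unique(pheno$strain)
  all_strains <- unique(c(s_tree, s_pa, s_ph))
  common <- s_tree[s_tree %in% s_pa & s_tree %in% s_ph]
  if (length(common) < 3L)
    stop("fewer than 3 strains shared by tree, matrix and phenotypes (",
         length(common), ")")
  sub <- pa[, common, drop = FALSE]
  rs <- rowSums(sub)
  invariant <- rs == 0L | rs == ncol(sub)
  if (all(invariant))
    stop("nothing to test: all genes invariant over the analysis strains")
  out <- list(
    strains = common,
    missing = list(
      tree = setdiff(all_strains, s_tree),
      pa_matrix = setdiff(all_strains, s_pa),
      phenotypes = setdiff(all_strains, s_ph)
    ),
    n_invariant = sum(invariant),
    scoreable_genes = rownames(sub)[!invariant]
  )
  class(out) <- "pan_validation"
  out
}

#' @export
print.pan_validation <- function(x, ...) {
  cat("Cross-validation of association inputs\n")
  cat("  analysis strains:", length(x$strains), "\n")
  n_missing <- lengths(x$missing)
  for (src in names(x$missing))
    if (n_missing[[src]] > 0L)
      cat(sprintf("  missing from %s: %s\n", src,
                  paste(x$missing[[src]], collapse = ", ")))
  if (all(n_missing == 0L)) cat("  strain sets agree across all sources\n")
  cat("  invariant genes excluded from scoring:", x$n_invariant, "\n")
  cat("  scoreable genes:", length(x$scoreable_genes), "\n")
  invisible(x)
}
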