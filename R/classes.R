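#' Expression matrix with tumor/normal condition labels
#'
#' Container for a genes x samples matrix of (log-scale) expression values
#' together with a tumor/normal label for every sample. Gene symbols are bare
#' strings, case-sensitive and whitespace-trimmed; no alias resolution is
#' attempted.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). Missing values are allowed until
#'   [impute_missing()] is applied.
#' @param condition Named character vector mapping every sample ID to
#'   `"tumor"` or `"normal"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `condition` (labels aligned to `colnames(values)`).
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
#' expression_matrix(m, c(S1 = "tumor", S2 = "tumor", S3 = "normal"))
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames")
  }
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  assert_unique(rownames(values), "gene symbol(s)")
  assert_unique(colnames(values), "sample ID(s)")
  condition <- unlist(condition)
  if (is.null(names(condition))) abort("`condition` must be named by sample ID")
  names(condition) <- trimws(names(condition))
  missing_cond <- setdiff(colnames(values), names(condition))
  if (length(missing_cond) > 0) {
    abort(sprintf(
      "sample(s) missing from condition map: %s",
      paste(head(missing_cond, 10), collapse = ", ")
    ))
  }
  condition <- as.character(condition[colnames(values)])
  names(condition) <- colnames(values)
  bad <- setdiff(unique(condition), c("tumor", "normal"))
  if (length(bad) > 0) {
    abort(sprintf(
      "condition labels must be 'tumor' or 'normal', got: %s",
      paste(bad, collapse = ", ")
    ))
  }
  structure(list(values = values, condition = condition), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples (%d tumor, %d normal), %d missing values\n",
    nrow(x$values), ncol(x$values),
    sum(x$condition == "tumor"), sum(x$condition == "normal"),
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @param which Condition to select samples for.
#' @export
condition_samples <- function(x, which = c("tumor", "normal")) {
  stopifnot(inherits(x, "expr_matrix"))
  which <- match.arg(which)
  names(x$condition)[x$condition == which]
}

#' Binary gene x sample alteration matrix
#'
#' A gene is marked altered (1) in a sample if it carries a somatic mutation
#' or a copy-number call passing the GISTIC threshold; see
#' [build_mutation_matrix()]. Per-gene counts are the number of altered
#' samples.
#'
#' @param M Binary (0/1) matrix with gene rownames and sample colnames.
#' @return An object of class `mut_matrix`: list with `M` (matrix) and
#'   `counts` (named integer vector, `rowSums(M)`).
#' @export
mutation_matrix <- function(M) {
  if (!is.matrix(M) || is.null(rownames(M)) || is.null(colnames(M))) {
    abort("`M` must be a matrix with gene rownames and sample colnames")
  }
  assert_unique(rownames(M), "gene symbol(s)")
  assert_unique(colnames(M), "sample ID(s)")
  if (!all(M %in% c(0L, 1L))) abort("`M` entries must be 0 or 1")
  storage.mode(M) <- "integer"
  structure(
    list(M = M, counts = setNames(as.integer(rowSums(M)), rownames(M))),
    class = "mut_matrix"
  )
}

#' @export
print.mut_matrix <- function(x, ...) {
  cat(sprintf(
    "<mut_matrix> %d genes x %d samples, %d altered (gene, sample) pairs\n",
    nrow(x$M), ncol(x$M), sum(x$M)
  ))
  invisible(x)
}

#' Collection of functional gene sets
#'
#' Named list of gene vectors (e.g. KEGG pathways and tumor-hallmark GO
#' terms). The union of all member genes defines the "functional genes" used
#' on the right side of the bipartite impact graph.
#'
#' @param sets Named list of character vectors. Set names must be unique;
#'   genes within a set are deduplicated.
#' @return An object of class `gene_sets` (the named list), with the union
#'   retrievable via [gene_set_union()].
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of character vectors")
  }
  assert_unique(names(sets), "gene set name(s)")
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    warn(sprintf("empty gene set(s) kept: %s", paste(empty, collapse = ", ")))
  }
  structure(sets, class = "gene_sets")
}

#' @rdname gene_set_collection
#' @param x A `gene_sets` collection.
#' @export
gene_set_union <- function(x) {
  stopifnot(inherits(x, "gene_sets"))
  unique(unlist(unclass(x), use.names = FALSE))
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf(
    "<gene_sets> %d sets, %d genes in union\n",
    length(x), length(gene_set_union(x))
  ))
  invisible(x)
}

# canonical undirected simple named graph used throughout
as_gene_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as.undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}
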