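#' Log2(x + 1) transform of raw expression values
#'
#' Raw RSEM abundances are mapped to `log2(v + 1)` per cell; missing cells
#' stay missing.
#'
#' @param x An [expression_matrix()] of raw values, or a bare numeric matrix.
#' @return Object of the same type with transformed values.
#' @export
log_transform <- function(x) {
  values <- if (inherits(x, "expr_matrix")) x$values else x
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "negative expression value for gene '%s', sample '%s'",
      rownames(values)[neg[1, 1]] %||% as.character(neg[1, 1]),
      colnames(values)[neg[1, 2]] %||% as.character(neg[1, 2])
    ))
  }
  out <- log2(values + 1)
  if (inherits(x, "expr_matrix")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Replace missing expression values by the gene mean
#'
#' Each missing cell is replaced by the mean of that gene's present values
#' across all samples (tumor and normal pooled); present cells are preserved
#' exactly.
#'
#' @param expr An [expression_matrix()] (or bare matrix).
#' @return Same type, with no missing values remaining.
#' @export
impute_missing <- function(expr) {
  values <- if (inherits(expr, "expr_matrix")) expr$values else expr
  n_present <- rowSums(!is.na(values))
  if (any(n_present == 0)) {
    abort(sprintf(
      "gene(s) with all values missing: %s",
      paste(head(rownames(values)[n_present == 0], 10), collapse = ", ")
    ))
  }
  idx <- which(is.na(values), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    gene_means <- rowMeans(values, na.rm = TRUE)
    values[idx] <- gene_means[idx[, 1]]
  }
  if (inherits(expr, "expr_matrix")) {
    expr$values <- values
    expr
  } else {
    values
  }
}

#' Build the binary alteration matrix from SNV and CNV evidence
#'
#' `M(i, j) = 1` iff gene `i` carries a somatic mutation in sample `j` or its
#' GISTIC call passes `|call| >= cnv_threshold` in sample `j`. When CNV data
#' are supplied the sample universe is the intersection of the SNV and CNV
#' sample sets and the gene universe the union of SNV genes and CNV matrix
#' rows; with SNV only, its own samples and genes are used.
#'
#' @param snv Tibble/data frame of `(gene, sample)` mutation events, e.g.
#'   from [read_maf()].
#' @param cnv Optional integer matrix of GISTIC calls (genes x samples), e.g.
#'   from [read_gistic()].
#' @param cnv_threshold 1 or 2; minimum `|call|` that counts as altered
#'   (default 2: high-level amplification / deep deletion only).
#' @return A [mutation_matrix()].
#' @export
build_mutation_matrix <- function(snv, cnv = NULL, cnv_threshold = 2) {
  if (!all(c("gene", "sample") %in% names(snv))) {
    abort("`snv` must have columns `gene` and `sample`")
  }
  if (!cnv_threshold %in% c(1L, 2L)) abort("`cnv_threshold` must be 1 or 2")
  snv <- distinct(tibble(
    gene = trimws(as.character(snv$gene)),
    sample = trimws(as.character(snv$sample))
  ))
  if (is.null(cnv)) {
    samples <- sort(unique(snv$sample))
    genes <- sort(unique(snv$gene))
  } else {
    samples <- sort(intersect(unique(snv$sample), colnames(cnv)))
    if (length(samples) == 0) {
      abort("no common samples between mutation and CNV data")
    }
    genes <- sort(union(unique(snv$gene), rownames(cnv)))
  }
  if (length(genes) == 0) abort("no genes in mutation input")
  M <- matrix(0L, length(genes), length(samples), dimnames = list(genes, samples))
  keep <- snv$sample %in% samples
  if (any(keep)) {
    M[cbind(
      match(snv$gene[keep], genes),
      match(snv$sample[keep], samples)
    )] <- 1L
  }
  if (!is.null(cnv)) {
    sub <- cnv[, samples, drop = FALSE]
    hit <- which(abs(sub) >= cnv_threshold, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      M[cbind(
        match(rownames(sub)[hit[, 1]], genes),
        match(colnames(sub)[hit[, 2]], samples)
      )] <- 1L
    }
  }
  mutation_matrix(M)
}

#' Per-gene alteration counts
#'
#' @param mut A [mutation_matrix()].
#' @return Named integer vector: number of altered samples per gene.
#' @export
mutation_counts <- function(mut) {
  stopifnot(inherits(mut, "mut_matrix"))
  setNames(as.integer(rowSums(mut$M)), rownames(mut$M))
}
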