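# Differential coexpression module.
#
# A gene's "links" are its PPI neighbors present in the expression matrix;
# the DCp statistic is the root-mean-square change in link Pearson
# correlations between tumor and normal, tested by permuting condition
# labels globally (one shuffle per round, all edges recomputed) so the null
# preserves cross-gene correlation structure.

# center rows and scale to unit norm over the given samples; constant rows
# are zeroed so downstream dot products give PCC = 0 for them (flagged)
row_unit_scale <- function(values, samples) {
  Z <- values[, samples, drop = FALSE]
  Z <- Z - rowMeans(Z)
  nrm <- sqrt(rowSums(Z^2))
  constant <- !is.finite(nrm) | nrm < .Machine$double.eps^0.5
  nrm[constant] <- 1
  Z <- Z / nrm
  if (any(constant)) Z[constant, ] <- 0
  list(Z = Z, constant = constant)
}

edge_dot <- function(Z, i, j) {
  unname(rowSums(Z[i, , drop = FALSE] * Z[j, , drop = FALSE]))
}

#' Pearson correlation of network edges within one condition
#'
#' Computes, for each gene pair, the Pearson correlation of expression over
#' the samples of one condition. A constant-expression gene yields a defined
#' PCC of 0 and is flagged via the `constant_genes` attribute.
#'
#' @param expr An [expression_matrix()] without missing values.
#' @param condition `"tumor"` or `"normal"`.
#' @param edges Two-column matrix or data frame of gene pairs; both genes
#'   must be present in `expr`.
#' @return Tibble with columns `gene_a`, `gene_b`, `pcc`; attribute
#'   `constant_genes` lists flagged genes.
#' @export
edge_pcc <- function(expr, condition = c("tumor", "normal"), edges) {
  stopifnot(inherits(expr, "expr_matrix"))
  condition <- match.arg(condition)
  if (any(is.na(expr$values))) abort("expression matrix has missing values; impute first")
  edges <- as.matrix(as.data.frame(edges)[, 1:2])
  storage.mode(edges) <- "character"
  samples <- condition_samples(expr, condition)
  if (length(samples) < 3) {
    abort(sprintf("need at least 3 '%s' samples, got %d", condition, length(samples)))
  }
  absent <- setdiff(unique(as.vector(edges)), rownames(expr$values))
  if (length(absent) > 0) {
    abort(sprintf(
      "edge gene(s) absent from expression matrix: %s",
      paste(head(absent, 10), collapse = ", ")
    ))
  }
  sc <- row_unit_scale(expr$values, samples)
  i <- match(edges[, 1], rownames(expr$values))
  j <- match(edges[, 2], rownames(expr$values))
  out <- tibble(
    gene_a = edges[, 1],
    gene_b = edges[, 2],
    pcc = edge_dot(sc$Z, i, j)
  )
  attr(out, "constant_genes") <- rownames(expr$values)[sc$constant]
  out
}

#' DCp: root-mean-square change in a gene's link correlations
#'
#' `dC = sqrt(mean((r_a - r_b)^2))` over the gene's links; lies in \[0, 2\].
#'
#' @param r_a,r_b Equal-length correlation vectors (entries in \[-1, 1\]),
#'   one entry per link, under the two conditions.
#' @return The scalar statistic.
#' @examples
#' dcp_statistic(c(1, 0), c(0, 0)) # sqrt(1/2)
#' @export
dcp_statistic <- function(r_a, r_b) {
  if (length(r_a) == 0 || length(r_b) == 0) abort("correlation vectors must be non-empty")
  if (length(r_a) != length(r_b)) abort("correlation vectors must have equal length")
  eps <- 1e-8
  if (any(abs(r_a) > 1 + eps) || any(abs(r_b) > 1 + eps)) {
    abort("correlations must lie in [-1, 1]")
  }
  sqrt(mean((r_a - r_b)^2))
}

# accumulate per-gene sums of squared correlation differences over incident
# edges; gi/gj are integer gene indices of edge endpoints
gene_dc_from_edges <- function(d2, gi, gj, n_genes, degree) {
  s <- numeric(n_genes)
  t1 <- rowsum(d2, gi)
  s[as.integer(rownames(t1))] <- t1[, 1]
  t2 <- rowsum(d2, gj)
  idx <- as.integer(rownames(t2))
  s[idx] <- s[idx] + t2[, 1]
  sqrt(s / pmax(degree, 1))
}

#' Differential coexpression test over a PPI network
#'
#' For every gene with at least one network link carrying expression data,
#' computes the observed DCp statistic, a permutation p-value obtained by
#' shuffling tumor/normal labels (group sizes preserved, all edge
#' correlations recomputed per shuffle), a Benjamini-Hochberg q-value, and
#' the DCG flag `q < fdr_threshold`.
#'
#' The p-value uses the add-one formula
#' `p = (1 + #\{permuted dC >= observed dC\}) / (n_perm + 1)` so it is never
#' exactly zero.
#'
#' @param expr An [expression_matrix()] without missing values.
#' @param network Undirected igraph PPI network.
#' @param n_perm Number of label permutations (default 199).
#' @param fdr_threshold DCG selection threshold on the q-value (default
#'   0.25).
#' @param seed Optional integer seed; same seed reproduces the p-vector
#'   exactly.
#' @return A `dcg_result` tibble: `gene`, `n_links`, `dC`, `p_value`,
#'   `q_value`, `is_dcg`, ordered by decreasing `dC`. Genes with no scored
#'   links are excluded and listed in the `excluded_genes` attribute.
#' @export
dcg_test <- function(expr, network, n_perm = 199, fdr_threshold = 0.25, seed = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  network <- as_gene_network(network)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (any(is.na(expr$values))) abort("expression matrix has missing values; impute first")
  genes_expr <- rownames(expr$values)
  shared <- intersect(igraph::V(network)$name, genes_expr)
  sub <- igraph::induced_subgraph(network, shared)
  em <- igraph::as_edgelist(sub)
  if (nrow(em) == 0) abort("no network edges with expression data on both endpoints")
  gi <- match(em[, 1], genes_expr)
  gj <- match(em[, 2], genes_expr)
  n_genes <- length(genes_expr)
  degree <- tabulate(gi, n_genes) + tabulate(gj, n_genes)
  scored <- which(degree > 0)
  excluded <- setdiff(shared, genes_expr[scored])
  if (length(excluded) > 0) {
    inform(sprintf("%d gene(s) with no scored links excluded", length(excluded)))
  }

  tum <- condition_samples(expr, "tumor")
  nor <- condition_samples(expr, "normal")
  if (length(tum) < 3 || length(nor) < 3) {
    abort("need at least 3 samples per condition")
  }
  values <- expr$values

  dc_for_labels <- function(tumor_samples, normal_samples) {
    rt <- edge_dot(row_unit_scale(values, tumor_samples)$Z, gi, gj)
    rn <- edge_dot(row_unit_scale(values, normal_samples)$Z, gi, gj)
    gene_dc_from_edges((rt - rn)^2, gi, gj, n_genes, degree)
  }

  dc_obs <- dc_for_labels(tum, nor)

  all_samples <- c(tum, nor)
  n_tum <- length(tum)
  exceed <- integer(n_genes)
  with_seed_if(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(all_samples), n_tum)
      dc_b <- dc_for_labels(all_samples[idx], all_samples[-idx])
      exceed <- exceed + (dc_b >= dc_obs)
    }
  })
  p <- (1 + exceed[scored]) / (n_perm + 1)
  q <- bh_adjust(p)
  res <- tibble(
    gene = genes_expr[scored],
    n_links = as.integer(degree[scored]),
    dC = dc_obs[scored],
    p_value = p,
    q_value = q,
    is_dcg = q < fdr_threshold
  ) |> arrange(desc(.data$dC), .data$gene)
  if (!any(res$is_dcg)) {
    warn("no differentially coexpressed genes at the chosen FDR threshold")
  }
  as_result_tibble(
    res,
    class = c("dcg_result", "tbl_df", "tbl", "data.frame"),
    n_perm = n_perm,
    fdr_threshold = fdr_threshold,
    excluded_genes = excluded,
    n_tumor = length(tum),
    n_normal = length(nor)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]) with input
#' validation: p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Vector of q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially coexpressed genes
#'
#' @param results A `dcg_result` from [dcg_test()].
#' @param fdr_threshold q-value cutoff (default 0.25).
#' @return Character vector of DCG symbols (`q < fdr_threshold`).
#' @export
select_dcgs <- function(results, fdr_threshold = 0.25) {
  stopifnot(all(c("gene", "q_value") %in% names(results)))
  out <- results$gene[results$q_value < fdr_threshold]
  if (length(out) == 0) warn("no genes pass the DCG FDR threshold")
  out
}
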