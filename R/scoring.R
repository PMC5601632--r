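# Bipartite impact scoring.
#
# DCGs (left) are linked to functional genes (right, the union of the
# functional gene sets) through PPI edges, each edge weighted by the
# magnitude of the tumor-condition Pearson correlation. A DCG's impact
# d_AF is its total edge weight into the functional side; its z-score is
# taken against a Monte-Carlo null that redraws the functional-gene label
# set uniformly from the network nodes (topology preserved).

# weighted star of every DCG: all its PPI neighbors that carry expression
# data, with the configured correlation weight
dcg_star_weights <- function(dcgs, network, expr,
                             weight_mode = c("abs_tumor", "signed_tumor", "abs_normal")) {
  weight_mode <- match.arg(weight_mode)
  network <- as_gene_network(network)
  nodes <- igraph::V(network)$name
  genes_expr <- rownames(expr$values)
  dropped <- setdiff(dcgs, nodes)
  left <- intersect(dcgs, intersect(nodes, genes_expr))
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d DCG(s) absent from the PPI network dropped: %s",
      length(dropped), paste(head(dropped, 10), collapse = ", ")
    ))
  }
  if (length(left) == 0) {
    return(list(
      edges = tibble(dcg = character(), neighbor = character(), weight = double()),
      left = left, dropped = dropped, network = network
    ))
  }
  inc <- igraph::incident_edges(network, left)
  pairs <- purrr::map2_dfr(left, inc, function(g, es) {
    if (length(es) == 0) {
      return(tibble(dcg = character(), neighbor = character()))
    }
    ends <- igraph::ends(network, es, names = TRUE)
    nb <- ifelse(ends[, 1] == g, ends[, 2], ends[, 1])
    tibble(dcg = g, neighbor = nb)
  })
  pairs <- pairs[pairs$neighbor %in% genes_expr & pairs$neighbor != pairs$dcg, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(edges = tibble(pairs, weight = double(0)), left = left, dropped = dropped, network = network))
  }
  cond <- if (weight_mode == "abs_normal") "normal" else "tumor"
  pcc <- edge_pcc(expr, cond, pairs[, c("dcg", "neighbor")])
  w <- if (weight_mode == "signed_tumor") pcc$pcc else abs(pcc$pcc)
  list(
    edges = tibble(dcg = pairs$dcg, neighbor = pairs$neighbor, weight = w),
    left = left, dropped = dropped, network = network
  )
}

#' Build the DCG / functional-gene bipartite impact graph
#'
#' Left nodes are DCGs, right nodes the union of the functional gene sets;
#' an edge (g, f) exists iff g and f interact in the PPI network. Genes
#' absent from the PPI network are dropped and reported. Edge weights are
#' `|PCC|` over tumor samples by default.
#'
#' @param dcgs Character vector of DCG symbols (e.g. from [select_dcgs()]).
#' @param fgs A [gene_set_collection()] of functional gene sets.
#' @param network Undirected igraph PPI network.
#' @param expr An [expression_matrix()] (tumor samples are used for the
#'   default weighting).
#' @param weight_mode `"abs_tumor"` (default), `"signed_tumor"` or
#'   `"abs_normal"`.
#' @return A `bipartite_graph` tibble with columns `dcg`, `functional`,
#'   `weight`; attributes `left` (all retained DCGs, including ones with no
#'   functional neighbor), `right` (functional genes on the network), and
#'   `dropped_dcgs`.
#' @export
build_bipartite <- function(dcgs, fgs, network, expr,
                            weight_mode = c("abs_tumor", "signed_tumor", "abs_normal")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(fgs, "gene_sets"))
  star <- dcg_star_weights(dcgs, network, expr, weight_mode)
  functional <- intersect(gene_set_union(fgs), igraph::V(star$network)$name)
  edges <- star$edges[star$edges$neighbor %in% functional, , drop = FALSE]
  edges <- rename(edges, functional = "neighbor")
  if (nrow(edges) == 0) {
    warn("empty bipartite graph: no DCG has a functional-gene PPI neighbor")
  }
  as_result_tibble(
    edges,
    class = c("bipartite_graph", "tbl_df", "tbl", "data.frame"),
    left = star$left,
    right = functional,
    dropped_dcgs = star$dropped,
    weight_mode = weight_mode
  )
}

#' Total weighted connectivity of a DCG to the functional genes
#'
#' `d_AF(g)` is the sum of bipartite edge weights from `g` into the
#' functional-gene side; 0 for a DCG with no functional neighbors.
#'
#' @param graph A `bipartite_graph` from [build_bipartite()].
#' @param gene A left-node (DCG) symbol.
#' @return Non-negative scalar.
#' @export
d_af <- function(graph, gene) {
  stopifnot(inherits(graph, "bipartite_graph"))
  left <- attr(graph, "left")
  if (!gene %in% left) abort(sprintf("'%s' is not a left (DCG) node", gene))
  sum(graph$weight[graph$dcg == gene])
}

#' DCG z-score against a resampled functional-gene null
#'
#' The observed `d_AF` of every DCG is compared with `n_null` Monte-Carlo
#' draws in which the functional-gene label set is replaced by a uniformly
#' random set of the same size drawn from the network nodes; the network
#' topology and edge weights stay fixed. `z = (d_AF - mean_null) / sd_null`
#' with the sample standard deviation (denominator `n_null - 1`); a
#' degenerate null (`sd = 0`) yields `z = 0` and is flagged.
#'
#' @inheritParams build_bipartite
#' @param n_null Number of null draws (default 100, must be >= 2).
#' @param fgs_size Optional override of the null set size (defaults to the
#'   number of functional genes present on the network).
#' @param seed Optional integer seed.
#' @return Tibble: `gene`, `n_functional_neighbors`, `d_af`, `mu_null`,
#'   `sd_null`, `z_dcg`, `degenerate_null`.
#' @export
dcg_zscore <- function(dcgs, fgs, network, expr, n_null = 100, fgs_size = NULL,
                       seed = NULL,
                       weight_mode = c("abs_tumor", "signed_tumor", "abs_normal")) {
  weight_mode <- match.arg(weight_mode)
  if (n_null < 2) abort("`n_null` must be >= 2")
  star <- dcg_star_weights(dcgs, network, expr, weight_mode)
  left <- star$left
  if (length(left) == 0) abort("no DCGs present on the network")
  nodes <- igraph::V(star$network)$name
  functional <- intersect(gene_set_union(fgs), nodes)
  size <- as.integer(fgs_size %||% length(functional))
  if (size < 1 || size > length(nodes)) {
    abort("functional-set size must be in 1..number of network nodes")
  }

  edges <- star$edges
  di <- match(edges$dcg, left)
  ni <- match(edges$neighbor, nodes)

  sum_by_dcg <- function(member) {
    # member: logical over nodes
    s <- numeric(length(left))
    keep <- member[ni]
    if (any(keep)) {
      t1 <- rowsum(edges$weight[keep], di[keep])
      s[as.integer(rownames(t1))] <- t1[, 1]
    }
    s
  }

  obs <- sum_by_dcg(nodes %in% functional)
  nulls <- matrix(0, length(left), n_null)
  with_seed_if(seed, {
    for (b in seq_len(n_null)) {
      draw <- logical(length(nodes))
      draw[sample.int(length(nodes), size)] <- TRUE
      nulls[, b] <- sum_by_dcg(draw)
    }
  })
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1, sd)
  degenerate <- sdev < .Machine$double.eps^0.5
  z <- ifelse(degenerate, 0, (obs - mu) / sdev)
  n_fn <- tabulate(di[edges$neighbor %in% functional], length(left))
  tibble(
    gene = left,
    n_functional_neighbors = as.integer(n_fn),
    d_af = obs,
    mu_null = mu,
    sd_null = sdev,
    z_dcg = z,
    degenerate_null = degenerate
  )
}

#' Mutation-recurrence z-score
#'
#' Standardizes per-gene alteration counts over all genes in the mutation
#' matrix: `z = (count - mean) / sd` with the sample standard deviation.
#' All-equal counts give `z = 0` for every gene (flagged via the
#' `degenerate` attribute).
#'
#' @param counts Named integer vector of per-gene alteration counts, e.g.
#'   from [mutation_counts()].
#' @return Named numeric vector of z-scores.
#' @export
mutation_zscore <- function(counts) {
  if (length(counts) < 2) abort("need counts for at least 2 genes")
  if (is.null(names(counts))) abort("`counts` must be named by gene")
  s <- sd(counts)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    z <- setNames(rep(0, length(counts)), names(counts))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (counts - mean(counts)) / s
  attr(z, "degenerate") <- FALSE
  setNames(as.numeric(z), names(counts))
}

#' Combine coexpression-impact and mutation z-scores into a ranked driver table
#'
#' `driver_score = z_dcg + z_mut`; a missing component contributes 0. The
#' default candidate universe is the DCGs (genes with a coexpression-impact
#' score); `candidates = "dcg_or_mutated"` additionally admits mutated
#' non-DCG genes present on the network with `z_dcg = 0`. Genes are ranked
#' by descending score, ties broken by higher alteration count, then
#' lexicographic gene symbol.
#'
#' @param z_dcg Tibble from [dcg_zscore()] or named numeric vector of DCG
#'   z-scores.
#' @param z_mut Named numeric vector from [mutation_zscore()].
#' @param counts Named integer vector of alteration counts
#'   ([mutation_counts()]).
#' @param n_tumor_samples Number of tumor samples, used for
#'   `alteration_fraction`.
#' @param score_threshold Candidate cutoff on the driver score (default 2).
#' @param candidates `"dcg"` (default) or `"dcg_or_mutated"`.
#' @param network Required for `candidates = "dcg_or_mutated"`: mutated
#'   genes must be network nodes to enter the universe.
#' @return A `driver_table` tibble: `gene`, `rank`, `z_dcg`, `z_mut`,
#'   `driver_score`, `n_mutated`, `alteration_fraction`, `is_candidate`,
#'   `is_rare` (NA until [flag_rare_drivers()]).
#' @export
driver_scores <- function(z_dcg, z_mut, counts, n_tumor_samples,
                          score_threshold = 2,
                          candidates = c("dcg", "dcg_or_mutated"),
                          network = NULL) {
  candidates <- match.arg(candidates)
  if (is.data.frame(z_dcg)) {
    stopifnot(all(c("gene", "z_dcg") %in% names(z_dcg)))
    z_dcg <- setNames(z_dcg$z_dcg, z_dcg$gene)
  }
  if (length(z_dcg) > 0 && is.null(names(z_dcg))) abort("`z_dcg` must be named by gene")
  universe <- names(z_dcg)
  if (candidates == "dcg_or_mutated") {
    if (is.null(network)) abort("`network` is required for candidates = 'dcg_or_mutated'")
    mutated <- names(counts)[counts >= 1]
    universe <- union(universe, intersect(mutated, igraph::V(as_gene_network(network))$name))
  }
  if (length(universe) == 0) abort("empty candidate universe")
  if (n_tumor_samples < 1) abort("`n_tumor_samples` must be >= 1")
  zd <- ifelse(universe %in% names(z_dcg), z_dcg[universe], 0)
  zm <- ifelse(universe %in% names(z_mut), z_mut[universe], 0)
  nm <- ifelse(universe %in% names(counts), counts[universe], 0L)
  res <- tibble(
    gene = universe,
    z_dcg = as.numeric(zd),
    z_mut = as.numeric(zm),
    driver_score = as.numeric(zd + zm),
    n_mutated = as.integer(nm),
    alteration_fraction = as.integer(nm) / n_tumor_samples
  ) |>
    arrange(desc(.data$driver_score), desc(.data$n_mutated), .data$gene) |>
    mutate(
      rank = row_number(),
      is_candidate = .data$driver_score >= score_threshold,
      is_rare = NA
    ) |>
    select(
      "gene", "rank", "z_dcg", "z_mut", "driver_score",
      "n_mutated", "alteration_fraction", "is_candidate", "is_rare"
    )
  as_result_tibble(
    res,
    class = c("driver_table", "tbl_df", "tbl", "data.frame"),
    score_threshold = score_threshold,
    n_tumor_samples = n_tumor_samples,
    candidates = candidates
  )
}
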