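# Dense-module detection on the driver neighborhood (MCODE-style) and local
# hypergeometric gene-set enrichment.

#' Induced subgraph of the top drivers and their interaction partners
#'
#' @param table A `driver_table`.
#' @param network Undirected igraph PPI network.
#' @param top_k Number of top-ranked genes to seed the subgraph (default
#'   50); a `top_k` beyond the table size uses the whole table with a
#'   warning.
#' @return Induced igraph subgraph on the top genes plus all their direct
#'   neighbors.
#' @export
driver_subgraph <- function(table, network, top_k = 50) {
  network <- as_gene_network(network)
  genes <- ranked_genes(table)
  if (top_k > length(genes)) {
    warn(sprintf("top_k = %d exceeds the table (%d genes); using all", top_k, length(genes)))
    top_k <- length(genes)
  }
  top <- intersect(genes[seq_len(top_k)], igraph::V(network)$name)
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(network, top),
    function(v) igraph::V(network)$name[v]
  )))
  igraph::induced_subgraph(network, union(top, nbrs))
}

# MCODE vertex weight: highest k-core number of the closed-neighborhood
# subgraph times the density of that highest k-core
mcode_vertex_weights <- function(graph) {
  nodes <- igraph::V(graph)$name
  w <- setNames(numeric(length(nodes)), nodes)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (v in seq_along(nodes)) {
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(graph, nb)
    if (igraph::ecount(sub) == 0) next
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= kmax))
    nv <- igraph::vcount(core_sub)
    if (nv < 2) next
    dens <- igraph::ecount(core_sub) / (nv * (nv - 1) / 2)
    w[v] <- kmax * dens
  }
  w
}

#' MCODE-style dense-module detection
#'
#' Three stages: (1) every vertex is weighted by the highest k-core number
#' of its closed-neighborhood subgraph times that core's density; (2)
#' complexes are grown greedily from the highest-weight unvisited seed,
#' admitting unvisited neighbors whose weight exceeds
#' `seed weight * (1 - vwp)`; (3) each complex is reduced to its
#' `k_core`-core (so every emitted module has minimum degree >= `k_core`)
#' and split into connected components; empty cores are discarded.
#' Equal-weight seeds are ordered lexicographically by gene symbol, making
#' the output deterministic.
#'
#' @param graph Simple undirected igraph.
#' @param k_core Core filter (default 2, i.e. every reported module
#'   survives the 2-core).
#' @param vwp Vertex weight percentage in \[0, 1\] controlling complex
#'   growth (default 0.2).
#' @return An `mcode_modules` tibble: `module`, `seed`, `score`
#'   (density x size), `n_members`, `members` (list column, sorted),
#'   ordered by decreasing score.
#' @export
mcode <- function(graph, k_core = 2, vwp = 0.2) {
  stopifnot(vwp >= 0, vwp <= 1)
  graph <- as_gene_network(graph)
  empty <- as_result_tibble(
    tibble(
      module = integer(), seed = character(), score = double(),
      n_members = integer(), members = list()
    ),
    class = c("mcode_modules", "tbl_df", "tbl", "data.frame")
  )
  if (igraph::vcount(graph) == 0) return(empty)
  nodes <- igraph::V(graph)$name
  w <- mcode_vertex_weights(graph)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  order_idx <- order(-w, nodes)
  seen <- logical(length(nodes))
  complexes <- list()
  seeds <- character()
  for (s in order_idx) {
    if (seen[s]) next
    threshold <- w[s] * (1 - vwp)
    members <- s
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      nb <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nb <- nb[!seen[nb] & w[nb] > threshold]
      if (length(nb) == 0) break
      seen[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    complexes[[length(complexes) + 1]] <- members
    seeds <- c(seeds, nodes[s])
  }
  rows <- list()
  for (ci in seq_along(complexes)) {
    sub <- igraph::induced_subgraph(graph, complexes[[ci]])
    cores <- igraph::coreness(sub)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= k_core))
    if (igraph::vcount(core_sub) == 0) next
    comp <- igraph::components(core_sub)
    for (cc in seq_len(comp$no)) {
      part <- igraph::induced_subgraph(core_sub, which(comp$membership == cc))
      members <- sort(igraph::V(part)$name)
      nv <- length(members)
      dens <- igraph::ecount(part) / (nv * (nv - 1) / 2)
      rows[[length(rows) + 1]] <- tibble(
        seed = seeds[ci], score = dens * nv,
        n_members = as.integer(nv), members = list(members)
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows) |> arrange(desc(.data$score), .data$seed)
  out <- mutate(out, module = row_number()) |>
    select("module", "seed", "score", "n_members", "members")
  as_result_tibble(out, class = c("mcode_modules", "tbl_df", "tbl", "data.frame"))
}

#' Local hypergeometric gene-set enrichment
#'
#' For each set, tests the overlap between the query genes and the set
#' (both intersected with the background) with the upper-tail
#' hypergeometric probability, adjusts across sets by Benjamini-Hochberg,
#' and flags sets with `q < alpha` (default 0.05).
#'
#' @param query Character vector of genes (e.g. candidate drivers or one
#'   module's members); entries outside `background` are dropped with a
#'   warning.
#' @param collections A [gene_set_collection()].
#' @param background Character vector defining the gene universe (e.g. all
#'   network nodes).
#' @param alpha Significance threshold on the q-value.
#' @return An `enrichment_result` tibble: `set`, `overlap`, `set_size`,
#'   `query_size`, `p_value`, `q_value`, `significant`, ordered by p-value.
#' @export
enrich <- function(query, collections, background, alpha = 0.05) {
  stopifnot(inherits(collections, "gene_sets"))
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the background dropped", length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) abort("empty query gene set")
  N <- length(background)
  rows <- purrr::imap(unclass(collections), function(genes, nm) {
    in_bg <- intersect(genes, background)
    k <- length(intersect(in_bg, query))
    tibble(
      set = nm,
      overlap = as.integer(k),
      set_size = length(in_bg),
      query_size = length(query),
      p_value = hypergeometric_overlap(N, length(in_bg), length(query), k)
    )
  })
  out <- bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha
  out <- arrange(out, .data$p_value, .data$set)
  as_result_tibble(
    out,
    class = c("enrichment_result", "tbl_df", "tbl", "data.frame"),
    background_size = N, alpha = alpha
  )
}
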