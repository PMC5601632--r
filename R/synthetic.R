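# Seeded synthetic-data generator.
#
# Emulates the statistical structure the method assumes at desk scale: a
# scale-free PPI network, tumor/normal expression in which planted driver
# genes have their edge correlations rewired, recurrent driver mutations on
# a passenger background, functional gene sets enriched for the planted
# drivers' neighbors, and an optional "long gene" decoy that is highly
# mutated but has neither coexpression rewiring nor functional-gene
# adjacency.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's reference simulation: 500 genes, 60 tumor
#' and 30 normal samples, preferential-attachment parameter 2, 15 gene sets
#' of 10-30 genes, 10 planted drivers with rewiring strength 0.8 and
#' mutation frequency 0.3 over a 1% passenger rate, baseline edge
#' correlation 0.6, and the decoy switched on with 3x the driver mutation
#' frequency.
#'
#' @param n_genes,n_tumor,n_normal Problem dimensions.
#' @param attachment Edges added per node by preferential attachment.
#' @param n_gene_sets,set_size_range Functional gene-set collection shape.
#' @param n_drivers Number of planted driver genes.
#' @param delta Rewiring strength in \[0, 1\]: probability that each
#'   planted-driver edge coupling is flipped or zeroed in tumors.
#' @param driver_freq Per-tumor-sample mutation probability of a planted
#'   driver.
#' @param passenger_rate Background per-gene, per-sample mutation
#'   probability.
#' @param rho Target Pearson correlation of a degree-1/degree-1 network
#'   edge in the normal condition.
#' @param include_decoy Add the highly mutated, non-rewired,
#'   non-functional-adjacent decoy gene.
#' @param decoy_freq_multiplier Decoy mutation frequency as a multiple of
#'   `driver_freq` (capped at 1).
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 500, n_tumor = 60, n_normal = 30,
                              attachment = 2, n_gene_sets = 15,
                              set_size_range = c(10, 30), n_drivers = 10,
                              delta = 0.8, driver_freq = 0.3,
                              passenger_rate = 0.01, rho = 0.6,
                              include_decoy = TRUE, decoy_freq_multiplier = 3,
                              seed = 1) {
  stopifnot(
    n_genes >= 10, n_drivers < n_genes, n_tumor >= 3, n_normal >= 3,
    delta >= 0, delta <= 1, driver_freq >= 0, driver_freq <= 1,
    passenger_rate >= 0, passenger_rate <= 1, rho > 0, rho < 1,
    length(set_size_range) == 2, set_size_range[1] <= set_size_range[2]
  )
  structure(
    list(
      n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
      attachment = attachment, n_gene_sets = n_gene_sets,
      set_size_range = set_size_range, n_drivers = n_drivers,
      delta = delta, driver_freq = driver_freq,
      passenger_rate = passenger_rate, rho = rho,
      include_decoy = include_decoy,
      decoy_freq_multiplier = decoy_freq_multiplier, seed = seed
    ),
    class = "sim_config"
  )
}

#' Generate a connected scale-free gene network
#'
#' Preferential attachment: the first `attachment + 1` nodes are joined as a
#' star, then every new node attaches to `attachment` distinct existing
#' nodes with probability proportional to degree, giving
#' `attachment * (n_genes - attachment)` edges, no self-loops, and a
#' connected graph.
#'
#' @param n_genes Number of nodes (>= 10).
#' @param attachment Edges per new node.
#' @param seed Optional integer seed.
#' @return Undirected simple igraph with node labels `G0001`, `G0002`, ...
#' @export
generate_network <- function(n_genes, attachment = 2, seed = NULL) {
  stopifnot(n_genes >= 10, attachment >= 1, attachment < n_genes)
  m <- as.integer(attachment)
  with_seed_if(seed, {
    deg <- integer(n_genes)
    ii <- integer(0)
    jj <- integer(0)
    # node m+1 connects to all of 1..m
    ii <- rep.int(m + 1L, m)
    jj <- seq_len(m)
    deg[seq_len(m)] <- 1L
    deg[m + 1L] <- m
    if (n_genes > m + 1L) {
      for (v in seq.int(m + 2L, n_genes)) {
        prev <- seq_len(v - 1L)
        targets <- sample(prev, m, prob = deg[prev])
        ii <- c(ii, rep.int(v, m))
        jj <- c(jj, targets)
        deg[targets] <- deg[targets] + 1L
        deg[v] <- m
      }
    }
    width <- max(4L, nchar(as.character(n_genes)))
    labels <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
    g <- igraph::make_empty_graph(n_genes, directed = FALSE)
    igraph::V(g)$name <- labels
    g <- igraph::add_edges(g, rbind(ii, jj))
    as_gene_network(g)
  })
}

#' Generate tumor/normal expression with planted coexpression rewiring
#'
#' Latent node-factor model: every gene `i` carries its own standard-normal
#' factor `f_i`, and
#' `x_i = a * f_i + b * sum over neighbors j of s_e * f_j + noise`, where
#' `s_e` is the coupling of edge `e = (i, j)` (1 in the normal condition)
#' and the noise is unit-variance Gaussian. Both endpoints load on each
#' other's factor, so an edge between two degree-2 genes has Pearson
#' correlation `2ab / (a^2 + 2 b^2 + 1)`; with the fixed neighbor coupling
#' `b = 2`, `a` is chosen so this modal-edge correlation equals `rho`
#' (capped at the model maximum `b / sqrt(2 b^2 + 1)` when `rho` exceeds
#' it). Higher-degree genes attenuate per-edge correlation through their
#' larger variance. In the tumor condition each edge incident to a planted
#' driver has its coupling, independently with probability `delta`, flipped
#' in sign (4:1 odds) or zeroed; all other couplings are unchanged.
#' Values are shifted by `+8` so they resemble log-scale expression.
#'
#' @param config A [simulation_config()].
#' @param network The gene network.
#' @param planted Character vector of planted driver genes (subset of the
#'   network nodes).
#' @param seed Optional integer seed.
#' @return An [expression_matrix()] with samples `T001...` and `N001...`.
#' @export
generate_expression <- function(config, network, planted, seed = NULL) {
  nodes <- igraph::V(network)$name
  stopifnot(all(planted %in% nodes))
  em <- igraph::as_edgelist(network, names = FALSE)
  n_e <- nrow(em)
  n_g <- length(nodes)
  # modal-edge correlation target: with neighbor coupling b, solve
  # 2ab/(a^2 + 2b^2 + 1) = rho for the smaller root of a; above the model
  # maximum b/sqrt(2b^2 + 1) use the maximizing a = sqrt(2b^2 + 1)
  b <- 2
  disc <- b^2 - config$rho^2 * (2 * b^2 + 1)
  a <- if (disc > 0) (b - sqrt(disc)) / config$rho else sqrt(2 * b^2 + 1)

  with_seed_if(seed, {
    planted_idx <- match(planted, nodes)
    s_normal <- rep(1, n_e)
    s_tumor <- s_normal
    incident <- which(em[, 1] %in% planted_idx | em[, 2] %in% planted_idx)
    if (length(incident) > 0) {
      rewire <- incident[runif(length(incident)) < config$delta]
      # sign reversal is the canonical differential-coexpression pattern;
      # a smaller share of rewired couplings is silenced instead
      mode <- runif(length(rewire)) < 0.8
      s_tumor[rewire[mode]] <- -1
      s_tumor[rewire[!mode]] <- 0
    }
    draw_condition <- function(n, coupling) {
      FF <- matrix(rnorm(n_g * n), n_g, n)
      X <- a * FF + matrix(rnorm(n_g * n), n_g, n)
      for (e in seq_len(n_e)) {
        if (coupling[e] == 0) next
        X[em[e, 1], ] <- X[em[e, 1], ] + b * coupling[e] * FF[em[e, 2], ]
        X[em[e, 2], ] <- X[em[e, 2], ] + b * coupling[e] * FF[em[e, 1], ]
      }
      X + 8
    }
    Xt <- draw_condition(config$n_tumor, s_tumor)
    Xn <- draw_condition(config$n_normal, s_normal)
    values <- cbind(Xt, Xn)
    rownames(values) <- nodes
    colnames(values) <- c(
      sprintf("T%03d", seq_len(config$n_tumor)),
      sprintf("N%03d", seq_len(config$n_normal))
    )
    condition <- setNames(
      rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)),
      colnames(values)
    )
    expression_matrix(values, condition)
  })
}

#' Generate the binary alteration matrix over tumor samples
#'
#' Every gene mutates per tumor sample with the passenger rate; planted
#' drivers additionally with `driver_freq`; the decoy (if any) with
#' `decoy_freq_multiplier * driver_freq` (capped at 1).
#'
#' @inheritParams generate_expression
#' @param decoy Optional decoy gene symbol.
#' @return A [mutation_matrix()] over genes x tumor samples.
#' @export
generate_mutations <- function(config, network, planted, decoy = NULL, seed = NULL) {
  nodes <- igraph::V(network)$name
  n_g <- length(nodes)
  n_t <- config$n_tumor
  with_seed_if(seed, {
    M <- matrix(rbinom(n_g * n_t, 1L, config$passenger_rate), n_g, n_t)
    rownames(M) <- nodes
    colnames(M) <- sprintf("T%03d", seq_len(n_t))
    for (g in planted) {
      M[g, ] <- pmax(M[g, ], rbinom(n_t, 1L, config$driver_freq))
    }
    if (!is.null(decoy)) {
      p_decoy <- min(1, config$decoy_freq_multiplier * config$driver_freq)
      M[decoy, ] <- pmax(M[decoy, ], rbinom(n_t, 1L, p_decoy))
    }
    mutation_matrix(M)
  })
}

#' Generate functional gene sets enriched for planted-driver neighbors
#'
#' Sets are sampled from the network nodes excluding the decoy and its
#' neighbors (so the decoy ends with zero functional neighbors). For each
#' planted driver, about half of its eligible neighbors (always at least
#' one) are forced into the union by appending them to random sets,
#' guaranteeing bipartite edges for the planted signal.
#'
#' @inheritParams generate_mutations
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(config, network, planted, decoy = NULL, seed = NULL) {
  nodes <- igraph::V(network)$name
  excluded <- character(0)
  if (!is.null(decoy)) {
    nb <- igraph::V(network)$name[igraph::neighbors(network, decoy)]
    excluded <- c(decoy, nb)
  }
  pool <- setdiff(nodes, excluded)
  with_seed_if(seed, {
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
      config$n_gene_sets,
      replace = TRUE
    )
    sets <- lapply(sizes, function(sz) sample(pool, min(sz, length(pool))))
    names(sets) <- sprintf("SET%02d", seq_along(sets))
    member_union <- unique(unlist(sets))
    for (g in planted) {
      nb <- igraph::V(network)$name[igraph::neighbors(network, g)]
      elig <- setdiff(intersect(nb, pool), g)
      if (length(elig) == 0) {
        abort(sprintf("planted driver %s has no eligible neighbor for the gene sets", g))
      }
      want <- max(1L, ceiling(length(elig) / 2))
      chosen <- if (length(elig) == 1) elig else sample(elig, want)
      for (f in setdiff(chosen, member_union)) {
        target <- sample.int(length(sets), 1)
        sets[[target]] <- c(sets[[target]], f)
        member_union <- c(member_union, f)
      }
    }
    gene_set_collection(sets)
  })
}

#' Generate a complete synthetic dataset
#'
#' Builds, from one master seed: the scale-free network, planted drivers
#' (sampled among nodes of degree >= 3), the decoy (degree >= 2,
#' non-planted, not adjacent to a planted driver), functional gene sets,
#' tumor/normal expression with rewiring, the alteration matrix, and the
#' benchmark list (the planted drivers).
#'
#' @param config A [simulation_config()].
#' @return A `sim_data` list: `config`, `network`, `planted`, `decoy`,
#'   `gene_sets`, `expression`, `mutations`, `benchmark`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), {
    network <- generate_network(config$n_genes, config$attachment)
    nodes <- igraph::V(network)$name
    deg <- igraph::degree(network)
    # drivers are planted on moderate-degree nodes with mostly low-degree
    # partners: under the latent-factor expression model per-edge correlation
    # attenuates with endpoint degree, so edges into extreme hubs carry
    # (unrealistically) little rewiring signal
    n_informative <- vapply(seq_along(nodes), function(v) {
      sum(deg[as.integer(igraph::neighbors(network, v))] <= 4)
    }, numeric(1))
    names(n_informative) <- nodes
    eligible <- nodes[deg >= 4 & deg <= 6 & n_informative >= deg - 2]
    if (length(eligible) < config$n_drivers) {
      eligible <- nodes[deg >= 3 & deg <= 6 & n_informative >= 2]
    }
    if (length(eligible) < config$n_drivers) {
      eligible <- nodes[deg >= 3 & deg <= 8 & n_informative >= 2]
    }
    if (length(eligible) < config$n_drivers) eligible <- nodes[deg >= 3]
    if (length(eligible) < config$n_drivers) {
      abort("not enough nodes of degree >= 3 to plant drivers")
    }
    planted <- sort(sample(eligible, config$n_drivers,
      prob = n_informative[eligible] + 1
    ))

    decoy <- NULL
    if (config$include_decoy) {
      # the decoy stays two hops away from every planted driver so that no
      # rewired edge touches its neighborhood: its mutation load is then the
      # only signal it carries, like a long passenger-mutated gene
      planted_nb <- unique(unlist(lapply(
        igraph::adjacent_vertices(network, planted),
        function(v) nodes[v]
      )))
      planted_nb2 <- unique(unlist(lapply(
        igraph::adjacent_vertices(network, planted_nb),
        function(v) nodes[v]
      )))
      cand <- setdiff(nodes[deg >= 2], c(planted, planted_nb, planted_nb2))
      if (length(cand) == 0) cand <- setdiff(nodes[deg >= 2], c(planted, planted_nb))
      cand <- sample(cand)
      for (d in cand) {
        d_closed <- c(d, nodes[igraph::neighbors(network, d)])
        ok <- all(vapply(planted, function(g) {
          nb <- nodes[igraph::neighbors(network, g)]
          length(setdiff(nb, c(d_closed, g))) >= 1
        }, logical(1)))
        if (ok) {
          decoy <- d
          break
        }
      }
      if (is.null(decoy)) abort("could not place a decoy gene")
    }

    gene_sets <- generate_gene_sets(config, network, planted, decoy)
    expression <- generate_expression(config, network, planted)
    mutations <- generate_mutations(config, network, planted, decoy)
    structure(
      list(
        config = config, network = network, planted = planted, decoy = decoy,
        gene_sets = gene_sets, expression = expression, mutations = mutations,
        benchmark = planted
      ),
      class = "sim_data"
    )
  })
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(
    "<sim_data> %d genes, %d tumor / %d normal samples, %d planted drivers%s\n",
    x$config$n_genes, x$config$n_tumor, x$config$n_normal,
    length(x$planted),
    if (is.null(x$decoy)) "" else sprintf(", decoy %s", x$decoy)
  ))
  invisible(x)
}

#' Write a synthetic dataset as an on-disk input bundle
#'
#' Writes the full set of pipeline inputs: expression TSV, condition map,
#' MAF-like mutation table, GISTIC-style gene-level call table (all-zero
#' calls: the simulated alterations are carried by the MAF), network edge
#' list, GMT gene sets, and the benchmark list (the planted drivers).
#'
#' @param sim A `sim_data` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    maf = file.path(dir, "mutations.maf"),
    gistic = file.path(dir, "cnv_gistic.tsv"),
    network = file.path(dir, "network.sif"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    benchmark = file.path(dir, "benchmark.txt")
  )

  vals <- sim$expression$values
  expr_df <- data.frame(gene = rownames(vals), apply(vals, 2, fmt_num),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  readr::write_tsv(expr_df, paths$expression, progress = FALSE)

  readr::write_tsv(
    data.frame(
      sample = names(sim$expression$condition),
      condition = unname(sim$expression$condition)
    ),
    paths$conditions,
    progress = FALSE
  )

  hit <- which(sim$mutations$M == 1L, arr.ind = TRUE)
  maf <- data.frame(
    Hugo_Symbol = rownames(sim$mutations$M)[hit[, 1]],
    Tumor_Sample_Barcode = colnames(sim$mutations$M)[hit[, 2]],
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE
  )
  maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode), , drop = FALSE]
  readr::write_tsv(maf, paths$maf, progress = FALSE)

  gz <- matrix(0L, nrow(sim$mutations$M), ncol(sim$mutations$M),
    dimnames = dimnames(sim$mutations$M)
  )
  readr::write_tsv(
    data.frame(gene = rownames(gz), gz, check.names = FALSE),
    paths$gistic,
    progress = FALSE
  )

  em <- igraph::as_edgelist(sim$network)
  readr::write_lines(paste(em[, 1], em[, 2], sep = "\t"), paths$network)

  gmt <- vapply(names(sim$gene_sets), function(nm) {
    paste(c(nm, "synthetic", sim$gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(gmt, paths$gene_sets)

  readr::write_lines(sim$benchmark, paths$benchmark)
  invisible(paths)
}
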