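make_bipartite <- function(edges, left, right) {
  out <- tibble::tibble(
    dcg = edges$dcg, functional = edges$functional, weight = edges$weight
  )
  structure(out,
    class = c("bipartite_graph", class(tibble::tibble())),
    left = left, right = right
  )
}

test_that("d_AF sums functional-neighbor weights only", {
  g <- make_bipartite(
    tibble::tibble(
      dcg = c("g", "g"), functional = c("f1", "f2"), weight = c(0.8, 0.3)
    ),
    left = c("g", "lonely"), right = c("f1", "f2")
  )
  # the 0.9-weight neighbor outside the functional set never enters the graph
  expect_equal(d_af(g, "g"), 1.1, tolerance = 1e-9)
  expect_equal(d_af(g, "lonely"), 0)
  expect_error(d_af(g, "f1"), "left")

  single <- make_bipartite(
    tibble::tibble(dcg = "g", functional = "f1", weight = 0.42),
    left = "g", right = "f1"
  )
  expect_equal(d_af(single, "g"), 0.42)
})

test_that("bipartite construction drops non-PPI genes and respects set membership", {
  net <- igraph::graph_from_edgelist(
    rbind(c("g", "f1"), c("g", "f2"), c("g", "n1"), c("f1", "f2")),
    directed = FALSE
  )
  set.seed(1)
  v <- matrix(rnorm(4 * 8), 4, 8,
    dimnames = list(c("g", "f1", "f2", "n1"), c(paste0("T", 1:5), paste0("N", 1:3)))
  )
  ex <- make_expr(v, paste0("T", 1:5), paste0("N", 1:3))
  fgs <- gene_set_collection(list(S1 = c("f1", "f2")))

  bg <- suppressMessages(build_bipartite(c("g", "ghost"), fgs, net, ex))
  expect_setequal(bg$functional, c("f1", "f2"))
  expect_equal(attr(bg, "dropped_dcgs"), "ghost")
  expect_true(all(bg$weight >= 0 & bg$weight <= 1))
  # weights are |tumor PCC|
  expect_equal(
    bg$weight[bg$functional == "f1"],
    abs(cor(v["g", 1:5], v["f1", 1:5])),
    tolerance = 1e-12
  )

  lonely_fgs <- gene_set_collection(list(S1 = "zzz"))
  expect_warning(
    empty <- suppressMessages(build_bipartite("g", lonely_fgs, net, ex)),
    "empty"
  )
  expect_equal(nrow(empty), 0)
})

test_that("d_AF is additive over disjoint set halves and monotone in the FGS", {
  sim <- small_sim()
  dcgs <- sim$planted
  fgs_all <- sim$gene_sets
  half <- gene_set_collection(list(H = gene_set_union(fgs_all)[
    seq_len(floor(length(gene_set_union(fgs_all)) / 2))
  ]))
  other <- gene_set_collection(list(O = setdiff(gene_set_union(fgs_all), gene_set_union(half))))
  b_all <- suppressMessages(suppressWarnings(
    build_bipartite(dcgs, fgs_all, sim$network, sim$expression)
  ))
  b_half <- suppressMessages(suppressWarnings(
    build_bipartite(dcgs, half, sim$network, sim$expression)
  ))
  b_other <- suppressMessages(suppressWarnings(
    build_bipartite(dcgs, other, sim$network, sim$expression)
  ))
  for (g in intersect(dcgs, attr(b_all, "left"))) {
    expect_equal(d_af(b_all, g), d_af(b_half, g) + d_af(b_other, g), tolerance = 1e-9)
    expect_gte(d_af(b_all, g), d_af(b_half, g))
  }
})

test_that("impact z-scores are seeded, centered under a random truth, and flag degeneracy", {
  sim <- small_sim()
  z1 <- suppressMessages(dcg_zscore(
    sim$planted, sim$gene_sets, sim$network, sim$expression,
    n_null = 50, seed = 9
  ))
  z2 <- suppressMessages(dcg_zscore(
    sim$planted, sim$gene_sets, sim$network, sim$expression,
    n_null = 50, seed = 9
  ))
  expect_identical(z1$z_dcg, z2$z_dcg)
  expect_error(
    suppressMessages(dcg_zscore(sim$planted, sim$gene_sets, sim$network,
      sim$expression,
      n_null = 1
    )),
    "n_null"
  )

  # replacing the true FGS by a random same-size draw de-centers nothing:
  # mean z over DCGs stays near 0
  nodes <- igraph::V(sim$network)$name
  set.seed(11)
  rand_fgs <- gene_set_collection(list(R = sample(
    nodes,
    length(intersect(gene_set_union(sim$gene_sets), nodes))
  )))
  zr <- suppressMessages(dcg_zscore(
    sim$planted, rand_fgs, sim$network, sim$expression,
    n_null = 100, seed = 12
  ))
  expect_lt(abs(mean(zr$z_dcg)), 0.5)
})

test_that("mutation z-scores standardize counts exactly", {
  z <- mutation_zscore(c(a = 1L, b = 2L, c = 3L))
  expect_equal(unname(z), c(-1, 0, 1), tolerance = 1e-9)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  zd <- mutation_zscore(c(a = 4L, b = 4L, c = 4L))
  expect_equal(as.numeric(zd), c(0, 0, 0))
  expect_true(attr(zd, "degenerate"))

  z1 <- mutation_zscore(c(a = 1L, b = 5L, c = 9L, d = 2L))
  z2 <- mutation_zscore(c(a = 11L, b = 15L, c = 19L, d = 12L))
  expect_equal(unname(z1), unname(z2), tolerance = 1e-12)

  expect_error(mutation_zscore(c(a = 1L)), "at least 2")
})

test_that("driver scores combine components, rank, and break ties as specified", {
  tab <- driver_scores(
    z_dcg = c(A = 1.5, B = 2.5, C = 3.0, D = 3.0),
    z_mut = c(A = 0.8, C = 0, D = 0),
    counts = c(A = 4L, C = 5L, D = 9L),
    n_tumor_samples = 100,
    score_threshold = 2
  )
  expect_equal(tab$gene[tab$rank == 1], "D") # tie on 3.0 broken by count 9 > 5
  expect_equal(tab$gene[tab$rank == 2], "C")
  a <- tab[tab$gene == "A", ]
  expect_equal(a$driver_score, 2.3)
  expect_true(a$is_candidate)
  b <- tab[tab$gene == "B", ]
  expect_equal(b$driver_score, 2.5) # unmutated: z_mut treated as 0
  expect_true(b$is_candidate)
  expect_equal(b$n_mutated, 0L)
  expect_equal(a$alteration_fraction, 0.04)
  expect_equal(sort(tab$rank), 1:4)

  expect_error(
    driver_scores(setNames(numeric(0), character(0)), c(A = 1), c(A = 1L), 10),
    "empty candidate universe"
  )
})

test_that("mutated non-DCG genes enter the universe only on request", {
  net <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "M")), directed = FALSE)
  zd <- c(A = 2.0)
  zm <- c(A = 0.1, M = 3.0, X = 1.0)
  cnt <- c(A = 1L, M = 9L, X = 2L)
  dcg_only <- driver_scores(zd, zm, cnt, 10)
  expect_equal(dcg_only$gene, "A")
  both <- driver_scores(zd, zm, cnt, 10, candidates = "dcg_or_mutated", network = net)
  # X is mutated but not a network node, so stays out
  expect_setequal(both$gene, c("A", "M"))
  expect_equal(both$z_dcg[both$gene == "M"], 0)
})
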