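test_that("preferential attachment gives the expected size and determinism", {
  g <- generate_network(50, 2, seed = 10)
  expect_equal(igraph::vcount(g), 50)
  expect_equal(igraph::ecount(g), 2 * (50 - 2))
  expect_true(igraph::is_connected(g))
  expect_equal(sum(igraph::which_loop(g)), 0)

  g2 <- generate_network(50, 2, seed = 10)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))

  big <- generate_network(500, 2, seed = 10)
  deg <- igraph::degree(big)
  expect_gt(max(deg), 3 * median(deg)) # heavy tail
})

test_that("expression generation is seeded and reacts to rewiring strength", {
  cfg0 <- simulation_config(n_genes = 80, n_tumor = 25, n_normal = 25, n_drivers = 4, delta = 0, seed = 5)
  net <- generate_network(80, 2, seed = 5)
  planted <- igraph::V(net)$name[igraph::degree(net) >= 3][1:4]

  e1 <- generate_expression(cfg0, net, planted, seed = 6)
  e2 <- generate_expression(cfg0, net, planted, seed = 6)
  expect_identical(e1$values, e2$values)
  expect_equal(ncol(e1$values), 50)

  # delta = 0: planted genes have null-level dC
  d0 <- suppressWarnings(suppressMessages(dcg_test(e1, net, n_perm = 49, seed = 7)))
  # delta = 1: every planted edge rewired; planted dC clearly exceeds the rest
  cfg1 <- simulation_config(n_genes = 80, n_tumor = 25, n_normal = 25, n_drivers = 4, delta = 1, seed = 5)
  e3 <- generate_expression(cfg1, net, planted, seed = 6)
  d1 <- suppressWarnings(suppressMessages(dcg_test(e3, net, n_perm = 49, seed = 7)))
  planted_dc1 <- d1$dC[d1$gene %in% planted]
  other_dc1 <- d1$dC[!d1$gene %in% planted]
  expect_gt(mean(planted_dc1), mean(other_dc1))
  planted_dc0 <- d0$dC[d0$gene %in% planted]
  expect_gt(mean(planted_dc1), mean(planted_dc0))
})

test_that("edge correlations in the normal condition sit near the design target", {
  cfg <- simulation_config(n_genes = 300, n_tumor = 200, n_normal = 200, n_drivers = 3, seed = 9)
  net <- generate_network(300, 2, seed = 9)
  ex <- generate_expression(cfg, net, character(0), seed = 10)
  nor <- names(ex$condition)[ex$condition == "normal"]
  deg <- igraph::degree(net)
  em <- igraph::as_edgelist(net)
  # informative edges: a leaf (degree-2) gene and a low-degree partner; the
  # node-factor model puts their correlation near 2ab/sqrt((a^2+2b^2+1)(a^2+4b^2+1))
  # ~ 0.47-0.52 for the default rho
  low <- em[
    (deg[em[, 1]] == 2 & deg[em[, 2]] <= 4) |
      (deg[em[, 2]] == 2 & deg[em[, 1]] <= 4), ,
    drop = FALSE
  ]
  expect_gt(nrow(low), 5)
  r <- apply(low, 1, function(e) cor(ex$values[e[1], nor], ex$values[e[2], nor]))
  expect_gt(mean(r), 0.35)
  expect_lt(mean(r), 0.65)
})

test_that("mutation generation respects frequencies and the decoy multiplier", {
  net <- generate_network(100, 2, seed = 2)
  planted <- igraph::V(net)$name[igraph::degree(net) >= 3][1:5]

  cfg_all <- simulation_config(
    n_genes = 100, n_tumor = 10, n_normal = 5, n_drivers = 5,
    driver_freq = 1, passenger_rate = 0, seed = 2
  )
  mm <- generate_mutations(cfg_all, net, planted, seed = 3)
  expect_equal(unname(mm$counts[planted]), rep(10L, 5))
  expect_equal(sum(mm$counts), 50L) # only planted rows are non-zero

  cfg <- simulation_config(
    n_genes = 100, n_tumor = 60, n_normal = 5, n_drivers = 5,
    driver_freq = 0.3, passenger_rate = 0, seed = 2
  )
  mm2 <- generate_mutations(cfg, net, planted, seed = 4)
  # binomial(60, 0.3) 99% envelope
  bounds <- qbinom(c(0.005, 0.995), 60, 0.3)
  expect_true(all(mm2$counts[planted] >= bounds[1] & mm2$counts[planted] <= bounds[2]))

  decoy <- setdiff(igraph::V(net)$name, planted)[1]
  mm3 <- generate_mutations(cfg, net, planted, decoy = decoy, seed = 5)
  expect_gt(mm3$counts[[decoy]], max(bounds)) # ~0.9 frequency
})

test_that("gene sets guarantee planted adjacency and decoy isolation", {
  sim <- small_sim()
  union <- gene_set_union(sim$gene_sets)
  nodes <- igraph::V(sim$network)$name
  for (g in sim$planted) {
    nb <- nodes[igraph::neighbors(sim$network, g)]
    expect_gte(length(intersect(nb, union)), 1)
  }
  decoy_nb <- nodes[igraph::neighbors(sim$network, sim$decoy)]
  expect_length(intersect(c(sim$decoy, decoy_nb), union), 0)
  sizes <- lengths(sim$gene_sets)
  expect_true(all(sizes >= sim$config$set_size_range[1]))
})

test_that("the full dataset is reproducible from its master seed", {
  cfg <- simulation_config(n_genes = 60, n_tumor = 10, n_normal = 8, n_drivers = 3, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$planted, s2$planted)
  expect_identical(s1$decoy, s2$decoy)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$mutations$M, s2$mutations$M)
  expect_identical(unclass(s1$gene_sets), unclass(s2$gene_sets))
  expect_false(s1$decoy %in% s1$planted)
})

test_that("the on-disk bundle round-trips through the readers", {
  sim <- small_sim()
  dir <- tempfile("bundle")
  paths <- write_bundle(sim, dir)
  ex <- read_expression(paths$expression, paths$conditions)
  expect_equal(dim(ex$values), dim(sim$expression$values))
  expect_equal(ex$values, sim$expression$values, tolerance = 1e-6)
  expect_equal(ex$condition, sim$expression$condition)

  snv <- read_maf(paths$maf)
  cnv <- read_gistic(paths$gistic)
  mm <- build_mutation_matrix(snv, cnv)
  # genes x (samples carrying at least one event) reproduce the counts
  expect_equal(mm$counts[rownames(mm$M)], sim$mutations$counts[rownames(mm$M)])

  net <- suppressMessages(read_network(paths$network))
  expect_equal(igraph::ecount(net), igraph::ecount(sim$network))
  gs <- read_gmt(paths$gene_sets)
  expect_setequal(gene_set_union(gs), gene_set_union(sim$gene_sets))
  expect_setequal(read_benchmark(paths$benchmark), sim$planted)
})
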