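test_that("edge correlations hit the closed-form cases", {
  v <- rbind(
    g1 = c(1, 2, 3, 0, 0, 1),
    g2 = c(2, 4, 6, 1, 1, 1),
    g3 = c(3, 2, 1, 5, 5, 5),
    g4 = c(1, 1, 1, 2, 3, 4)
  )
  colnames(v) <- c(paste0("T", 1:3), paste0("N", 1:3))
  ex <- make_expr(v, paste0("T", 1:3), paste0("N", 1:3))
  edges <- rbind(c("g1", "g2"), c("g1", "g3"), c("g4", "g1"))
  pcc <- edge_pcc(ex, "tumor", edges)
  expect_equal(pcc$pcc, c(1, -1, 0), tolerance = 1e-12)
  # the constant gene is flagged
  expect_true("g4" %in% attr(pcc, "constant_genes"))

  expect_error(edge_pcc(ex, "tumor", rbind(c("g1", "gX"))), "gX")
  two <- make_expr(v[, c(1, 2, 4, 5, 6)], paste0("T", 1:2), paste0("N", 1:3))
  expect_error(edge_pcc(two, "tumor", edges), "at least 3")
})

test_that("DCp statistic matches hand-derived values", {
  expect_equal(dcp_statistic(c(0.9, -0.8, 0.1), c(0.9, -0.8, 0.1)), 0)
  expect_equal(dcp_statistic(c(1, 0), c(0, 0)), sqrt(1 / 2), tolerance = 1e-9)
  expect_equal(
    dcp_statistic(c(0.6, -0.2, 0.3), c(0.1, 0.2, 0.1)),
    sqrt(0.45 / 3),
    tolerance = 1e-9
  )
  expect_error(dcp_statistic(numeric(0), numeric(0)), "non-empty")
  expect_error(dcp_statistic(c(0.1, 0.2), 0.1), "equal length")
  expect_error(dcp_statistic(1.5, 0.2), "\\[-1, 1\\]")
})

test_that("DCp is symmetric and invariant to link ordering", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    ra <- runif(n, -1, 1)
    rb <- runif(n, -1, 1)
    o <- sample(n)
    expect_equal(dcp_statistic(ra, rb), dcp_statistic(rb, ra))
    expect_equal(dcp_statistic(ra, rb), dcp_statistic(ra[o], rb[o]))
    expect_gte(dcp_statistic(ra, rb), 0)
    expect_lte(dcp_statistic(ra, rb), 2 + 1e-12)
  }
})

test_that("BH adjustment reproduces step-up values and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-9)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5), tolerance = 1e-9)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("permutation p-values are reproducible, floored, and never zero", {
  sim <- small_sim()
  d1 <- suppressWarnings(suppressMessages(
    dcg_test(sim$expression, sim$network, n_perm = 29, seed = 5)
  ))
  d2 <- suppressWarnings(suppressMessages(
    dcg_test(sim$expression, sim$network, n_perm = 29, seed = 5)
  ))
  expect_identical(d1$p_value, d2$p_value)
  expect_true(all(d1$p_value >= 1 / 30))
  expect_true(all(d1$p_value <= 1))
  expect_true(all(d1$dC >= 0))
  expect_equal(sort(unique(c(d1$gene))), sort(intersect(
    igraph::V(sim$network)$name, rownames(sim$expression$values)
  )))
})

test_that("a gene whose links never change has a large permutation p", {
  # constant-dC gene: identical tumor/normal generative model (delta = 0)
  cfg <- simulation_config(
    n_genes = 60, n_tumor = 12, n_normal = 12, n_drivers = 2,
    delta = 0, seed = 3
  )
  sim <- simulate_dataset(cfg)
  d <- suppressWarnings(suppressMessages(
    dcg_test(sim$expression, sim$network, n_perm = 49, seed = 8)
  ))
  # under the null the p-value distribution is roughly uniform
  expect_gt(mean(d$p_value), 0.3)
})

test_that("DCG selection applies the FDR threshold", {
  res <- tibble::tibble(gene = c("a", "b"), q_value = c(0.1, 0.3))
  expect_equal(select_dcgs(res, 0.25), "a")
  expect_equal(select_dcgs(res, 1.0), c("a", "b"))
  expect_warning(out <- select_dcgs(tibble::tibble(gene = "a", q_value = 1), 0.25))
  expect_length(out, 0)
})
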