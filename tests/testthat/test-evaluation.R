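test_that("precision/recall/F1 match the closed forms", {
  ranked <- c("g1", "g2", "g3", "g4", "g5")
  bench <- c("g1", "g3", "x1", "x2")
  m <- precision_recall_f1(ranked, bench, 5)
  expect_equal(m$precision, 0.4)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 * 0.4 * 0.5 / 0.9, tolerance = 1e-9)

  perfect <- precision_recall_f1(c("a", "b"), c("a", "b"), 2)
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]), c(
    precision = 1, recall = 1, f1 = 1
  ))

  none <- precision_recall_f1(c("a", "b"), c("z"), 2)
  expect_equal(none$f1, 0) # 0/0 convention

  expect_error(precision_recall_f1(ranked, character(0), 2), "empty")
  expect_error(precision_recall_f1(ranked, bench, 6), "k")
})

test_that("evaluation curves are monotone and truncate oversized k", {
  ranked <- c("h1", "m1", "h2", "m2", "h3")
  bench <- c("h1", "h2", "h3")
  cur <- evaluation_curve(ranked, bench, c(1, 2, 3, 4, 5))
  expect_equal(cur$cumulative_hits, c(1, 1, 2, 2, 3))
  expect_true(all(diff(cur$cumulative_hits) >= 0))
  expect_true(all(diff(cur$recall) >= 0))
  expect_equal(cur$recall[5], 1) # benchmark fully contained in the list

  all_hits <- evaluation_curve(c("a", "b"), c("a", "b", "c"), c(1, 2))
  expect_equal(all_hits$cumulative_hits, c(1, 2))

  expect_warning(tr <- evaluation_curve(ranked, bench, c(2, 10)), "truncated")
  expect_equal(max(tr$k), 5)
  expect_error(evaluation_curve(ranked, bench, c(3, 1)), "ascending")
})

test_that("hypergeometric tail matches counting identities", {
  expect_equal(hypergeometric_overlap(10, 5, 5, 0), 1)
  expect_equal(hypergeometric_overlap(10, 5, 5, 5), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(6, 3, 3, 2), 0.5, tolerance = 1e-12)
  expect_error(hypergeometric_overlap(10, 11, 5, 2), "infeasible")
  expect_error(hypergeometric_overlap(10, 5, 5, 6), "infeasible")
})

test_that("hypergeometric tail agrees with exhaustive enumeration", {
  # literal enumeration over every size-n draw from N elements, M marked
  enum_tail <- function(N, M, n, k) {
    if (n == 0) {
      return(as.numeric(k == 0))
    }
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= M) # elements 1..M are the marked ones
    mean(hits >= k)
  }
  set.seed(7)
  cases <- 0
  for (N in c(4, 7, 9, 12)) {
    for (M in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (k in unique(c(0, 1, min(M, n)))) {
          if (k > min(M, n)) next
          p <- hypergeometric_overlap(N, M, n, k)
          e <- enum_tail(N, M, n, k)
          expect_equal(p, e, tolerance = 1e-12)
          cases <- cases + 1
        }
      }
    }
  }
  expect_gt(cases, 100)
})

test_that("rare-driver flagging applies exactly the three criteria", {
  tab <- tibble::tibble(
    gene = paste0("g", 1:8),
    rank = c(5, 5, 40, 40, 5, 5, 40, 40),
    alteration_fraction = c(0.0048, 0.0048, 0.001, 0.001, 0.5, 0.5, 0.5, 0.5),
    is_rare = NA
  )
  bench <- paste0("g", c(2, 4, 6, 8))
  out <- flag_rare_drivers(tab, bench)
  # brute-force truth table over (rank ok) x (freq ok) x (in benchmark)
  truth <- tab$rank <= 30 & tab$alteration_fraction < 0.02 & !tab$gene %in% bench
  expect_equal(out$is_rare, truth)
  expect_equal(out$is_rare, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("relaxing any rare-driver cutoff never un-flags a gene", {
  set.seed(21)
  tab <- tibble::tibble(
    gene = paste0("g", 1:60),
    rank = sample(60),
    alteration_fraction = runif(60, 0, 0.1),
    is_rare = NA
  )
  bench <- sample(tab$gene, 10)
  base <- flag_rare_drivers(tab, bench, rank_cutoff = 30, freq_cutoff = 0.02)$is_rare
  wider_rank <- flag_rare_drivers(tab, bench, rank_cutoff = 50, freq_cutoff = 0.02)$is_rare
  wider_freq <- flag_rare_drivers(tab, bench, rank_cutoff = 30, freq_cutoff = 0.05)$is_rare
  smaller_bench <- flag_rare_drivers(tab, bench[1:3], rank_cutoff = 30, freq_cutoff = 0.02)$is_rare
  expect_true(all(wider_rank[base]))
  expect_true(all(wider_freq[base]))
  expect_true(all(smaller_bench[base]))
})

test_that("the frequency baseline ranks by count with deterministic ties", {
  r <- rank_by_frequency(c(b = 3L, a = 3L, c = 9L))
  expect_equal(r$gene, c("c", "a", "b"))
  expect_equal(r$rank, 1:3)
})
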