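# Benchmarking against a known-driver list (e.g. a CGC export), overlap
# significance, rare-driver flagging, and the trivial mutation-frequency
# baseline.

ranked_genes <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot("gene" %in% names(ranked))
    if ("rank" %in% names(ranked)) ranked <- ranked[order(ranked$rank), , drop = FALSE]
    ranked$gene
  } else {
    as.character(ranked)
  }
}

#' Precision, recall and F1 of a top-k driver list
#'
#' `precision = hits / k`, `recall = hits / |benchmark|`,
#' `f1 = 2PR / (P + R)` (defined 0 when `P + R = 0`), where `hits` is the
#' overlap of the top-k ranked genes with the benchmark. To mirror the
#' benchmark formula "mutated genes in CGC", restrict the benchmark to genes
#' present in the mutation matrix before calling (see [run_pipeline()]).
#'
#' @param ranked Ranked gene character vector or a `driver_table`.
#' @param benchmark Character vector of known driver symbols.
#' @param k Top-list size, `1 <= k <= length(ranked)`.
#' @return Named list: `precision`, `recall`, `f1`, `hits`.
#' @export
precision_recall_f1 <- function(ranked, benchmark, k) {
  genes <- ranked_genes(ranked)
  benchmark <- unique(benchmark)
  if (length(benchmark) == 0) abort("benchmark list is empty")
  if (k < 1 || k > length(genes)) abort("`k` must lie in 1..length(ranked)")
  hits <- length(intersect(genes[seq_len(k)], benchmark))
  precision <- hits / k
  recall <- hits / length(benchmark)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, hits = hits)
}

#' Benchmark curve over several top-list sizes
#'
#' @inheritParams precision_recall_f1
#' @param ks Ascending vector of top-list sizes (e.g. `c(25, 50, 75, 100)`);
#'   sizes beyond the list length are truncated with a warning.
#' @return An `evaluation_curve` tibble: `k`, `cumulative_hits`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluation_curve <- function(ranked, benchmark, ks) {
  genes <- ranked_genes(ranked)
  if (is.unsorted(ks)) abort("`ks` must be sorted ascending")
  over <- ks > length(genes)
  if (any(over)) {
    warn(sprintf("k values beyond the ranked list truncated to %d", length(genes)))
    ks <- unique(pmin(ks, length(genes)))
  }
  rows <- purrr::map(ks, function(k) {
    m <- precision_recall_f1(genes, benchmark, k)
    tibble(
      k = as.integer(k), cumulative_hits = as.integer(m$hits),
      precision = m$precision, recall = m$recall, f1 = m$f1
    )
  })
  as_result_tibble(
    bind_rows(rows),
    class = c("evaluation_curve", "tbl_df", "tbl", "data.frame"),
    n_benchmark = length(unique(benchmark))
  )
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `k` common genes when a size-`n` set is
#' drawn from `N` genes of which `M` belong to the other set:
#' `P(X >= k)`, computed in log space via [stats::phyper()].
#'
#' @param N Background size (total genes).
#' @param M Size of the first set.
#' @param n Size of the second set.
#' @param k Observed overlap.
#' @return The tail probability.
#' @export
hypergeometric_overlap <- function(N, M, n, k) {
  if (any(c(N, M, n, k) != round(c(N, M, n, k)))) abort("arguments must be integers")
  if (N < 0 || M < 0 || n < 0 || k < 0 || M > N || n > N || k > min(M, n)) {
    abort("infeasible hypergeometric arguments")
  }
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Flag rare candidate drivers
#'
#' A gene is a rare driver iff it is ranked in the top `rank_cutoff`
#' (default 30), altered in fewer than `freq_cutoff` (default 2%) of tumor
#' samples, and absent from the benchmark list.
#'
#' @param table A `driver_table` with `rank` and `alteration_fraction`.
#' @param benchmark Character vector of known driver symbols.
#' @param rank_cutoff,freq_cutoff The three-criteria thresholds.
#' @return The table with `is_rare` filled in.
#' @export
flag_rare_drivers <- function(table, benchmark, rank_cutoff = 30, freq_cutoff = 0.02) {
  stopifnot(all(c("gene", "rank", "alteration_fraction") %in% names(table)))
  table$is_rare <- table$rank <= rank_cutoff &
    table$alteration_fraction < freq_cutoff &
    !table$gene %in% benchmark
  table
}

#' Trivial mutation-frequency baseline ranking
#'
#' Ranks genes by alteration count alone (ties by gene symbol), the
#' frequency-based comparator for the integrative score.
#'
#' @param mut A [mutation_matrix()] or named count vector.
#' @return Tibble: `gene`, `n_mutated`, `rank`.
#' @export
rank_by_frequency <- function(mut) {
  counts <- if (inherits(mut, "mut_matrix")) mutation_counts(mut) else mut
  tibble(gene = names(counts), n_mutated = as.integer(counts)) |>
    arrange(desc(.data$n_mutated), .data$gene) |>
    mutate(rank = row_number())
}
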