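# End-to-end orchestration: preprocess -> differential coexpression ->
# bipartite impact + mutation scoring -> benchmarking -> modules.

#' Prioritize driver genes from in-memory objects
#'
#' Runs the scoring pipeline on already-loaded data: differential
#' coexpression test, DCG selection, bipartite impact z-score, mutation
#' z-score, combined ranking, optional benchmark evaluation and rare-driver
#' flagging.
#'
#' @param expr An [expression_matrix()] (log scale; missing values are
#'   imputed by gene mean).
#' @param mut A [mutation_matrix()].
#' @param network Undirected igraph PPI network.
#' @param fgs A [gene_set_collection()].
#' @param benchmark Optional character vector of known drivers; when
#'   supplied, the evaluation restricts it to genes altered in the mutation
#'   matrix (the "mutated genes in the benchmark") unless
#'   `restrict_benchmark = FALSE`.
#' @param n_perm,fdr_threshold Permutations and q-value cutoff of the DCG
#'   stage.
#' @param n_null Monte-Carlo draws of the impact null.
#' @param score_threshold Candidate driver cutoff (default 2).
#' @param weight_mode Bipartite edge weighting (see [build_bipartite()]).
#' @param candidates Candidate universe (see [driver_scores()]).
#' @param rank_cutoff,freq_cutoff Rare-driver criteria.
#' @param ks Top-list sizes of the evaluation curve.
#' @param restrict_benchmark Restrict the benchmark to mutated genes for
#'   evaluation (default TRUE).
#' @param seed Integer seed governing the permutation and Monte-Carlo
#'   stages.
#' @return List with elements `dcg` (`dcg_result`), `dcgs` (selected
#'   genes), `impact` (z-score table), `drivers` (`driver_table`), `curve`
#'   (`evaluation_curve` or NULL), `overlap_p` (hypergeometric p of the
#'   candidate/benchmark overlap, or NULL).
#' @export
prioritize_drivers <- function(expr, mut, network, fgs, benchmark = NULL,
                               n_perm = 199, fdr_threshold = 0.25,
                               n_null = 100, score_threshold = 2,
                               weight_mode = "abs_tumor",
                               candidates = "dcg",
                               rank_cutoff = 30, freq_cutoff = 0.02,
                               ks = c(10, 25, 50, 100),
                               restrict_benchmark = TRUE, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(mut, "mut_matrix"))
  network <- as_gene_network(network)
  if (any(is.na(expr$values))) expr <- impute_missing(expr)

  with_seed_if(seed, {
    dcg <- dcg_test(expr, network,
      n_perm = n_perm, fdr_threshold = fdr_threshold, seed = NULL
    )
    dcgs <- dcg$gene[dcg$is_dcg]
    impact <- NULL
    z_dcg <- setNames(numeric(0), character(0))
    if (length(dcgs) > 0) {
      impact <- dcg_zscore(dcgs, fgs, network, expr,
        n_null = n_null, seed = NULL, weight_mode = weight_mode
      )
      z_dcg <- setNames(impact$z_dcg, impact$gene)
    }
    counts <- mutation_counts(mut)
    z_mut <- mutation_zscore(counts)
    drivers <- driver_scores(
      z_dcg, z_mut, counts,
      n_tumor_samples = ncol(mut$M),
      score_threshold = score_threshold,
      candidates = candidates, network = network
    )

    curve <- NULL
    overlap_p <- NULL
    if (!is.null(benchmark)) {
      bm <- unique(benchmark)
      bm_eval <- if (restrict_benchmark) {
        intersect(bm, names(counts)[counts >= 1])
      } else {
        bm
      }
      if (length(bm_eval) == 0) {
        warn("no benchmark gene is altered in the mutation matrix; using the full list")
        bm_eval <- bm
      }
      drivers <- flag_rare_drivers(drivers, bm,
        rank_cutoff = rank_cutoff, freq_cutoff = freq_cutoff
      )
      curve <- evaluation_curve(drivers, bm_eval, ks[ks <= nrow(drivers)])
      n_cand <- sum(drivers$is_candidate)
      if (n_cand > 0) {
        hits <- length(intersect(drivers$gene[drivers$is_candidate], bm_eval))
        N_bg <- igraph::vcount(network)
        overlap_p <- hypergeometric_overlap(
          N_bg, length(intersect(bm_eval, igraph::V(network)$name)),
          n_cand, min(hits, n_cand)
        )
      }
    }
    list(
      dcg = dcg, dcgs = dcgs, impact = impact, drivers = drivers,
      curve = curve, overlap_p = overlap_p
    )
  })
}

write_result_tsv <- function(df, path, num_cols) {
  out <- as.data.frame(df)
  for (cc in intersect(num_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the full pipeline from input files
#'
#' Reads every input, executes preprocess, differential coexpression,
#' scoring, optional benchmark evaluation, and optional module
#' detection/enrichment, and writes all result tables plus a JSON manifest
#' recording every parameter and seed to `output_dir`. Given the same
#' inputs and seed, the written numeric outputs are byte-identical across
#' runs.
#'
#' @param expression,conditions,maf,network,gene_sets Paths to the
#'   expression TSV, condition map, MAF-like mutation table, PPI edge list,
#'   and GMT file.
#' @param gistic Optional path to GISTIC gene-level thresholded calls.
#' @param benchmark Optional path to a known-driver list; when absent the
#'   evaluation stage is skipped with a warning.
#' @param output_dir Directory for the result files (created if needed).
#' @param cnv_threshold Minimum `|GISTIC call|` treated as an alteration.
#' @param log_transform_expression Set `TRUE` when the expression file
#'   holds raw (RSEM-like) values to apply `log2(x + 1)` first.
#' @param run_modules Run MCODE modules + enrichment on the top drivers.
#' @param top_k_modules Top-list size of the module subgraph (default 50).
#' @param mcode_k_core,mcode_vwp MCODE parameters.
#' @param enrich_alpha Enrichment significance threshold (default 0.05).
#' @inheritParams prioritize_drivers
#' @return Invisibly, the [prioritize_drivers()] result list plus
#'   `modules`, `enrichment`, and `paths` (the written files).
#' @export
run_pipeline <- function(expression, conditions, maf, network, gene_sets,
                         gistic = NULL, benchmark = NULL,
                         output_dir,
                         n_perm = 199, fdr_threshold = 0.25, n_null = 100,
                         score_threshold = 2, cnv_threshold = 2,
                         weight_mode = "abs_tumor", candidates = "dcg",
                         rank_cutoff = 30, freq_cutoff = 0.02,
                         ks = c(10, 25, 50, 100),
                         log_transform_expression = FALSE,
                         run_modules = TRUE, top_k_modules = 50,
                         mcode_k_core = 2, mcode_vwp = 0.2,
                         enrich_alpha = 0.05, seed = 1) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, code) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)))
    })
    message(sprintf(
      "[coexdriver] %-12s done in %.1fs", what,
      proc.time()[["elapsed"]] - t1
    ))
    res
  }

  inputs <- stage("io", {
    list(
      expr = read_expression(expression, conditions),
      snv = read_maf(maf),
      net = read_network(network),
      fgs = read_gmt(gene_sets),
      cnv = if (!is.null(gistic)) read_gistic(gistic) else NULL,
      bm = if (!is.null(benchmark)) read_benchmark(benchmark) else NULL
    )
  })
  if (is.null(inputs$bm)) {
    warn("no benchmark list supplied: evaluation stage will be skipped")
  }

  prep <- stage("preprocess", {
    expr <- inputs$expr
    if (log_transform_expression) expr <- log_transform(expr)
    expr <- impute_missing(expr)
    mut <- build_mutation_matrix(inputs$snv, inputs$cnv, cnv_threshold)
    list(expr = expr, mut = mut)
  })

  res <- stage("scoring", {
    prioritize_drivers(
      prep$expr, prep$mut, inputs$net, inputs$fgs,
      benchmark = inputs$bm,
      n_perm = n_perm, fdr_threshold = fdr_threshold, n_null = n_null,
      score_threshold = score_threshold, weight_mode = weight_mode,
      candidates = candidates, rank_cutoff = rank_cutoff,
      freq_cutoff = freq_cutoff, ks = ks, seed = seed
    )
  })

  modules <- NULL
  enrichment <- NULL
  if (run_modules && nrow(res$drivers) > 0) {
    modules <- stage("modules", {
      sub <- driver_subgraph(res$drivers, inputs$net, top_k = min(top_k_modules, nrow(res$drivers)))
      mcode(sub, k_core = mcode_k_core, vwp = mcode_vwp)
    })
    enrichment <- stage("enrichment", {
      cand <- res$drivers$gene[res$drivers$is_candidate]
      if (length(cand) == 0) cand <- head(res$drivers$gene, top_k_modules)
      enrich(
        intersect(cand, igraph::V(inputs$net)$name),
        inputs$fgs,
        background = igraph::V(inputs$net)$name,
        alpha = enrich_alpha
      )
    })
  }

  paths <- stage("write", {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      drivers = file.path(output_dir, "drivers.tsv"),
      dcgs = file.path(output_dir, "dcgs.tsv"),
      manifest = file.path(output_dir, "manifest.json")
    )
    write_driver_table(res$drivers, p$drivers)
    write_result_tsv(res$dcg, p$dcgs, c("dC", "p_value", "q_value"))
    if (!is.null(res$curve)) {
      p$curve <- file.path(output_dir, "curve.tsv")
      write_result_tsv(res$curve, p$curve, c("precision", "recall", "f1"))
    }
    if (!is.null(modules)) {
      p$modules <- file.path(output_dir, "modules.tsv")
      flat <- tidy(modules)
      write_result_tsv(flat, p$modules, "score")
    }
    if (!is.null(enrichment)) {
      p$enrichment <- file.path(output_dir, "enrichment.tsv")
      write_result_tsv(enrichment, p$enrichment, c("p_value", "q_value"))
    }
    manifest <- list(
      package = "coexdriver",
      version = as.character(utils::packageVersion("coexdriver")),
      inputs = list(
        expression = expression, conditions = conditions, maf = maf,
        network = network, gene_sets = gene_sets, gistic = gistic,
        benchmark = benchmark
      ),
      parameters = list(
        n_perm = n_perm, fdr_threshold = fdr_threshold, n_null = n_null,
        score_threshold = score_threshold, cnv_threshold = cnv_threshold,
        weight_mode = weight_mode, candidates = candidates,
        rank_cutoff = rank_cutoff, freq_cutoff = freq_cutoff, ks = ks,
        log_transform_expression = log_transform_expression,
        run_modules = run_modules, top_k_modules = top_k_modules,
        mcode_k_core = mcode_k_core, mcode_vwp = mcode_vwp,
        enrich_alpha = enrich_alpha
      ),
      seed = seed
    )
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE, null = "null")
    p
  })
  message(sprintf(
    "[coexdriver] pipeline finished in %.1fs", proc.time()[["elapsed"]] - t0
  ))
  invisible(c(res, list(modules = modules, enrichment = enrichment, paths = paths)))
}
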