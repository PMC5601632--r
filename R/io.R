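#' Read a genes x samples expression table with condition labels
#'
#' Expression values are read as-is (typically log2(RSEM+1); use
#' [log_transform()] for raw values). Orientation is fixed as genes-in-rows:
#' first column gene symbols, header row sample IDs. Missing-value tokens
#' `"NA"`, `"NaN"` and the empty cell are recorded as missing, never as zero;
#' imputation is a separate step ([impute_missing()]).
#'
#' @param path TSV file, first column gene symbols, remaining columns one per
#'   sample.
#' @param condition_path Two-column TSV with header `sample<TAB>condition`
#'   mapping every sample ID to `tumor` or `normal`.
#' @return An [expression_matrix()] with conditions attached.
#' @export
read_expression <- function(path, condition_path) {
  df <- readr::read_tsv(
    path,
    na = c("NA", "NaN", ""),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE,
    progress = FALSE
  )
  # first column holds the gene symbols whatever its header says
  genes <- trimws(df[[1]])
  assert_unique(genes, "gene symbol(s)")
  raw <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric expression value '%s' for gene '%s', sample '%s'",
      raw[bad[1, , drop = FALSE]], genes[bad[1, 1]], colnames(raw)[bad[1, 2]]
    ))
  }
  dimnames(values) <- list(genes, colnames(raw))
  cond <- readr::read_tsv(
    condition_path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  if (ncol(cond) < 2) abort("condition file must have two columns: sample, condition")
  condition <- setNames(trimws(cond[[2]]), trimws(cond[[1]]))
  expression_matrix(values, condition)
}

#' Read somatic mutation calls from a MAF-like table
#'
#' Only the `Hugo_Symbol` and `Tumor_Sample_Barcode` columns are used; all
#' other columns (including `Variant_Classification`) are ignored, i.e. no
#' variant-class filtering is applied by default. Multiple variants of one
#' gene in one sample collapse to a single (gene, sample) event.
#'
#' @param path Tab-separated file with at least columns `Hugo_Symbol` and
#'   `Tumor_Sample_Barcode`.
#' @param exclude_silent If `TRUE` and a `Variant_Classification` column is
#'   present, rows classified `Silent` are dropped before deduplication.
#' @return Tibble with columns `gene`, `sample`, one row per unique event.
#' @export
read_maf <- function(path, exclude_silent = FALSE) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE, comment = "#"
  )
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("MAF is missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  if (exclude_silent && "Variant_Classification" %in% names(df)) {
    df <- df[df$Variant_Classification != "Silent", , drop = FALSE]
  }
  tibble(
    gene = trimws(df$Hugo_Symbol),
    sample = trimws(df$Tumor_Sample_Barcode)
  ) |> distinct()
}

#' Read GISTIC gene-level thresholded copy-number calls
#'
#' Expects the gene-level thresholded-calls layout: a gene column followed by
#' one column per sample, every cell an integer call in -2..2 (+-2 denoting
#' high-level amplification / deep deletion).
#'
#' @param path TSV file as above.
#' @return Integer matrix, genes x samples.
#' @export
read_gistic <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  genes <- trimws(df[[1]])
  assert_unique(genes, "gene symbol(s)")
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(raw, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(raw), dimnames = dimnames(raw))
  if (any(is.na(num))) abort("GISTIC calls must be numeric")
  if (any(num != round(num))) abort("GISTIC calls must be integers (found non-integer value)")
  if (any(num < -2 | num > 2)) abort("GISTIC calls must lie in -2..2")
  calls <- matrix(as.integer(num), nrow = nrow(raw))
  dimnames(calls) <- list(genes, trimws(colnames(raw)))
  calls
}

#' Read an undirected protein-protein interaction network
#'
#' Accepts a two-column TSV edge list (`a<TAB>b`) or SIF
#' (`a<TAB>type<TAB>b1<TAB>b2...`). Self-interactions are removed and
#' duplicate edges collapse regardless of orientation; counts of dropped
#' records are reported via [message()].
#'
#' @param path Edge-list file, one interaction record per line.
#' @return An undirected simple [igraph::igraph] with gene-symbol vertex
#'   names.
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    warn("empty network file: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  pairs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1]]
    if (length(tok) < 2) {
      abort(sprintf("network line %d has fewer than 2 fields", i))
    }
    if (length(tok) == 2) {
      pairs[[i]] <- cbind(tok[1], tok[2])
    } else {
      # SIF: source, interaction type, one or more targets
      pairs[[i]] <- cbind(tok[1], tok[3:length(tok)])
    }
  }
  em <- do.call(rbind, pairs)
  n_records <- nrow(em)
  self <- em[, 1] == em[, 2]
  em <- em[!self, , drop = FALSE]
  # canonical orientation so (a,b) and (b,a) collapse
  key <- ifelse(em[, 1] <= em[, 2],
    paste(em[, 1], em[, 2], sep = "\r"),
    paste(em[, 2], em[, 1], sep = "\r")
  )
  dup <- duplicated(key)
  em <- em[!dup, , drop = FALSE]
  inform(sprintf(
    "read %d interaction records: %d self-interactions and %d duplicates dropped, %d edges kept",
    n_records, sum(self), sum(dup), nrow(em)
  ))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  as_gene_network(g)
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: per line a set name, a description, then the member
#' genes, all tab-separated. Sets with zero members are kept with a warning.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  sets <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 2) {
      abort(sprintf("GMT line %d is malformed (fewer than 2 fields)", i))
    }
    nm <- trimws(tok[1])
    if (nm %in% names(sets)) abort(sprintf("duplicate gene set name: %s", nm))
    members <- if (length(tok) > 2) tok[3:length(tok)] else character()
    sets[[nm]] <- members[trimws(members) != ""]
  }
  gene_set_collection(sets)
}

#' Read a benchmark driver-gene list
#'
#' @param path Plain-text file, one gene symbol per line (e.g. a CGC export).
#' @return Character vector of unique symbols.
#' @export
read_benchmark <- function(path) {
  genes <- unique(trimws(readr::read_lines(path, progress = FALSE)))
  genes <- genes[genes != ""]
  if (length(genes) == 0) abort("benchmark list is empty")
  genes
}

driver_table_columns <- c(
  "gene", "rank", "z_dcg", "z_mut", "driver_score",
  "n_mutated", "alteration_fraction", "is_rare"
)

#' Write / read a ranked driver table
#'
#' Numeric columns are written with 6 decimals so that re-reading reproduces
#' the table bit-exactly at the written precision and identical runs produce
#' byte-identical files.
#'
#' @param table A `driver_table` (see [driver_scores()]).
#' @param path Output TSV path.
#' @return `write_driver_table()` returns `path` invisibly;
#'   `read_driver_table()` returns the table as a `driver_table` tibble.
#' @export
write_driver_table <- function(table, path) {
  missing <- setdiff(driver_table_columns, names(table))
  if (length(missing) > 0) {
    abort(sprintf("driver table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  out <- table[order(table$rank), driver_table_columns, drop = FALSE]
  df <- data.frame(
    gene = out$gene,
    rank = as.integer(out$rank),
    z_dcg = fmt_num(out$z_dcg),
    z_mut = fmt_num(out$z_mut),
    driver_score = fmt_num(out$driver_score),
    n_mutated = as.integer(out$n_mutated),
    alteration_fraction = fmt_num(out$alteration_fraction),
    is_rare = ifelse(is.na(out$is_rare), "NA", ifelse(out$is_rare, "TRUE", "FALSE")),
    stringsAsFactors = FALSE
  )
  tryCatch(
    readr::write_tsv(df, path, progress = FALSE),
    error = function(e) abort(sprintf("cannot write driver table to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' @rdname write_driver_table
#' @export
read_driver_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      rank = readr::col_integer(),
      z_dcg = readr::col_double(),
      z_mut = readr::col_double(),
      driver_score = readr::col_double(),
      n_mutated = readr::col_integer(),
      alteration_fraction = readr::col_double(),
      is_rare = readr::col_logical()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  as_result_tibble(df, class = c("driver_table", "tbl_df", "tbl", "data.frame"))
}
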