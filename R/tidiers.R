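# broom-style tidiers for the result types

#' @exportS3Method generics::tidy
tidy.dcg_result <- function(x, ...) as_tibble(as.data.frame(x))

#' @exportS3Method generics::glance
glance.dcg_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_dcgs = sum(x$is_dcg),
    min_q = if (nrow(x)) min(x$q_value) else NA_real_,
    n_perm = attr(x, "n_perm") %||% NA_integer_,
    fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_,
    n_tumor = attr(x, "n_tumor") %||% NA_integer_,
    n_normal = attr(x, "n_normal") %||% NA_integer_
  )
}

#' @exportS3Method generics::tidy
tidy.driver_table <- function(x, ...) as_tibble(as.data.frame(x))

#' @exportS3Method generics::glance
glance.driver_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_candidates = if ("is_candidate" %in% names(x)) sum(x$is_candidate) else NA_integer_,
    n_rare = if (all(is.na(x$is_rare))) NA_integer_ else sum(x$is_rare, na.rm = TRUE),
    top_score = if (nrow(x)) max(x$driver_score) else NA_real_,
    score_threshold = attr(x, "score_threshold") %||% NA_real_,
    n_tumor_samples = attr(x, "n_tumor_samples") %||% NA_integer_
  )
}

#' @exportS3Method generics::tidy
tidy.evaluation_curve <- function(x, ...) {
  as_tibble(as.data.frame(x)) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
      names_to = "metric", values_to = "value"
    )
}

#' @exportS3Method generics::glance
glance.evaluation_curve <- function(x, ...) {
  tibble(
    n_points = nrow(x),
    max_recall = if (nrow(x)) max(x$recall) else NA_real_,
    max_f1 = if (nrow(x)) max(x$f1) else NA_real_,
    n_benchmark = attr(x, "n_benchmark") %||% NA_integer_
  )
}

#' @exportS3Method generics::tidy
tidy.mcode_modules <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(
      module = integer(), seed = character(),
      score = double(), gene = character()
    ))
  }
  tidyr::unnest(
    select(as_tibble(as.data.frame(x)), "module", "seed", "score", "members"),
    "members"
  ) |> rename(gene = "members")
}

#' @exportS3Method generics::glance
glance.mcode_modules <- function(x, ...) {
  tibble(
    n_modules = nrow(x),
    largest = if (nrow(x)) max(x$n_members) else NA_integer_,
    top_score = if (nrow(x)) max(x$score) else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) as_tibble(as.data.frame(x))

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    background_size = attr(x, "background_size") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}
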