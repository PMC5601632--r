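# in-code fixtures shared across test files

make_expr <- function(values, tumor, normal) {
  condition <- setNames(
    rep(c("tumor", "normal"), c(length(tumor), length(normal))),
    c(tumor, normal)
  )
  expression_matrix(values, condition)
}

# tiny expression matrix: 4 genes x 6 samples (3 tumor, 3 normal)
tiny_expr <- function() {
  set.seed(99)
  v <- matrix(rnorm(24), 4, 6,
    dimnames = list(paste0("g", 1:4), c(paste0("T", 1:3), paste0("N", 1:3)))
  )
  make_expr(v, paste0("T", 1:3), paste0("N", 1:3))
}

# 5-clique {A..E} with a pendant 3-path E-F-G-H
clique_path_graph <- function() {
  clique <- t(utils::combn(LETTERS[1:5], 2))
  path <- cbind(c("E", "F", "G"), c("F", "G", "H"))
  igraph::graph_from_edgelist(rbind(clique, path), directed = FALSE)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small but complete simulated dataset reused by several files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(
        n_genes = 150, n_tumor = 20, n_normal = 15, n_drivers = 5, seed = 77
      ))
    }
    cache
  }
})
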