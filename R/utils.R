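# internal helpers shared across modules

# evaluate `code` under a temporary RNG seed when one is supplied; the
# caller's RNG state is untouched either way unless seed is NULL
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# fixed-precision formatting used by every writer so that identical runs
# produce byte-identical files (6 decimals, "." decimal mark, no sci notation)
fmt_num <- function(x, digits = 6L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NA"
  out
}

assert_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate %s: %s", what,
      paste(head(dup, 10), collapse = ", ")
    ))
  }
  invisible(x)
}

# new_tibble wrapper that keeps extra attributes on a classed tibble
as_result_tibble <- function(df, class, ...) {
  out <- new_tibble(df, nrow = nrow(df), class = class)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}
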