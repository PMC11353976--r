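# Shared small helpers.

#' Time-bin index of an event
#'
#' Maps days-before-anchor to a 0-indexed six-month bin. Bin `n_bins - 1` is
#' adjacent to the anchor and covers days `[0, bin_days)`; intervals are
#' half-open `(older, newer]` in calendar terms, so an event exactly
#' `bin_days` days before the anchor falls in bin `n_bins - 2`. Days beyond
#' the covered window return `NA`.
#'
#' @param days_before_anchor Non-negative integer vector.
#' @param n_bins Number of bins (default 10).
#' @param bin_days Bin width in days (default 183, a six-month segment).
#' @return Integer bin indices in `0:(n_bins - 1)`, or `NA`.
#' @export
bin_of_days <- function(days_before_anchor, n_bins = 10L, bin_days = 183L) {
  b <- n_bins - 1L - as.integer(days_before_anchor %/% bin_days)
  b[b < 0L | days_before_anchor < 0] <- NA_integer_
  b
}

#' Read/write long event tables and cohort tables as headered TSV
#'
#' @param x A tibble.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_event_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_event_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname tsv_io
#' @export
write_cohort_table <- write_event_table

#' @rdname tsv_io
#' @export
read_cohort_table <- read_event_table

# Stratified fold assignment: within each class, cycle fold labels over a
# seeded permutation. Returns an integer vector in 1:k.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Deterministic RNG scope: evaluates expr with a local seed without
# clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
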