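# internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of the given length; vectorised over columns
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  if (len == 0L) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# geometric mean of a positive vector
geomean <- function(x) exp(mean(log(x)))

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` must contain column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
}

# long (barcode x sample) tibble -> base matrix, zero-filled
counts_to_matrix <- function(counts, value = "count") {
  stopifnot_cols(counts, c("barcode", "sample_id", value), "counts")
  wide <- tidyr::pivot_wider(counts[, c("barcode", "sample_id", value)],
                             names_from = "sample_id",
                             values_from = all_of(value),
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$barcode
  m
}

sample_meta_cols <- function() {
  c("cell_line", "condition", "nk_genotype", "timepoint", "well", "techrep")
}

# distinct per-sample metadata from a long counts tibble
meta_from_counts <- function(counts) {
  distinct(counts, across(any_of(c("sample_id", sample_meta_cols()))))
}
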