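# shared builders for simulated fixtures

small_config <- function(n_clones = 50, seed = 42, ...) {
  generator_config(n_clones = n_clones, seed = seed, ...)
}

# a tiny merged long count tibble for two conditions at one timepoint
toy_counts <- function(mat_alone, mat_nk, timepoint = "TP2") {
  stopifnot(nrow(mat_alone) == nrow(mat_nk))
  bcs <- sprintf("bc%03d", seq_len(nrow(mat_alone)))
  make <- function(m, condition) {
    purrr::map(seq_len(ncol(m)), function(w) {
      tibble::tibble(barcode = bcs,
                     sample_id = sprintf("%s_%s_w%d", condition, timepoint, w),
                     condition = condition, timepoint = timepoint,
                     well = w, count = m[, w])
    }) |> dplyr::bind_rows()
  }
  dplyr::bind_rows(make(mat_alone, "alone"), make(mat_nk, "nk"))
}

# independent step-up BH oracle (direct definition)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(ord)]
}

# write a FASTQ file from raw sequence strings
write_test_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  ids <- sprintf("@read%d", seq_along(seqs))
  writeLines(c(rbind(ids, seqs, "+", strrep("I", nchar(seqs)))), path)
  path
}
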