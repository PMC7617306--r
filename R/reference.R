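#' Build the reference barcode set from viral-library samples
#'
#' Defines the whitelist of true library barcodes: sequences whose summed
#' read count across the viral-library samples reaches `min_total_reads`
#' (inclusive, default 100 across the usual four library samples).
#'
#' @param library_counts Long tibble of library-sample counts (`barcode`,
#'   `sample_id`, `count`), or a list of `extraction_result`s, one per
#'   library sample.
#' @param min_total_reads Minimum summed count across library samples.
#' @return Tibble of class `barcode_reference` with columns `barcode` and
#'   `total_reads`, sorted by decreasing total. The number of library
#'   samples is kept in attribute `n_library_samples`.
#' @examples
#' lib <- tibble::tibble(barcode = rep(c("AAA", "CCC"), each = 2),
#'                       sample_id = rep(c("s1", "s2"), 2),
#'                       count = c(60, 40, 99, 0))
#' build_reference(lib)   # keeps AAA (sum 100), drops CCC (sum 99)
#' @export
build_reference <- function(library_counts, min_total_reads = 100) {
  if (is.list(library_counts) && !is.data.frame(library_counts)) {
    if (length(library_counts) < 1) abort("need at least one library sample")
    library_counts <- purrr::imap(library_counts, function(res, i) {
      mutate(tidy(res), sample_id = sprintf("library_s%s", i))
    }) %>% bind_rows()
  }
  stopifnot_cols(library_counts, c("barcode", "sample_id", "count"),
                 "library_counts")
  ref <- library_counts %>%
    group_by(.data$barcode) %>%
    summarise(total_reads = sum(.data$count), .groups = "drop") %>%
    filter(.data$total_reads >= min_total_reads) %>%
    arrange(dplyr::desc(.data$total_reads), .data$barcode)
  attr(ref, "n_library_samples") <- length(unique(library_counts$sample_id))
  attr(ref, "min_total_reads") <- min_total_reads
  class(ref) <- c("barcode_reference", class(ref))
  ref
}

#' Restrict observed counts to the reference barcode set
#'
#' Drops counts for barcodes absent from the reference (exact string match)
#' and tallies the dropped reads per sample as the off-reference tally,
#' attached as attribute `"off_reference"` and retrievable with
#' [off_reference()]. Matched counts plus the tally conserve the input
#' totals per sample.
#'
#' @param counts Long count tibble (`barcode`, `sample_id`, `count`, any
#'   metadata columns), e.g. from [count_sample()] results or
#'   [simulate_coculture()].
#' @param reference A [build_reference()] result (or anything with a
#'   `barcode` column).
#' @return The filtered counts tibble, with attribute `off_reference`: a
#'   tibble `sample_id`, `reads_dropped`.
#' @export
match_to_reference <- function(counts, reference) {
  stopifnot_cols(counts, c("barcode", "sample_id", "count"), "counts")
  keep <- counts$barcode %in% reference$barcode
  off <- counts[!keep, ] %>%
    group_by(.data$sample_id) %>%
    summarise(reads_dropped = sum(.data$count), .groups = "drop")
  # samples with nothing dropped still get an explicit zero tally
  all_samples <- unique(counts$sample_id)
  off <- tidyr::complete(off, sample_id = all_samples,
                         fill = list(reads_dropped = 0))
  out <- counts[keep, ]
  attr(out, "off_reference") <- off
  out
}

#' @rdname match_to_reference
#' @param x A tibble returned by [match_to_reference()].
#' @export
off_reference <- function(x) {
  attr(x, "off_reference", exact = TRUE)
}

#' @export
print.barcode_reference <- function(x, ...) {
  cat(sprintf("<barcode_reference> %d barcodes (>= %g reads across %d library samples)\n",
              nrow(x), attr(x, "min_total_reads"),
              attr(x, "n_library_samples")))
  NextMethod()
}

#' Export reference barcodes as FASTA
#'
#' @param reference A [build_reference()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reference$barcode,
                                            reference$barcode))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
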