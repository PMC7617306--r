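#' Status levels reported by barcode extraction
#'
#' QC categories assigned to each read: `accepted`, or the first applicable
#' rejection among `rejected_no_head`, `rejected_no_tail`,
#' `rejected_length`, `rejected_uncalled`.
#'
#' @format Character vector of length 5.
#' @export
EXTRACT_STATUS <- c("accepted", "rejected_length", "rejected_uncalled",
                    "rejected_no_head", "rejected_no_tail")

#' Locate barcodes between fixed anchors
#'
#' Pattern-matches each read for the first occurrence of the head anchor,
#' then the first occurrence of the tail anchor downstream of it, and takes
#' the substring strictly between them as the barcode. Matching is exact
#' (no mismatches) and position-free: bases before the head do not affect
#' the result. A read is rejected when either anchor is absent, the insert
#' does not have the expected length, or it contains an uncalled base (N).
#' Base qualities play no role.
#'
#' @param reads Character vector of read sequences.
#' @param head,tail Anchor sequences (non-empty).
#' @param expected_length Required barcode length (>= 1; default 21).
#' @return Tibble with one row per read: `barcode` (`NA` when rejected) and
#'   `status`, a factor over [EXTRACT_STATUS].
#' @examples
#' extract_barcodes(paste0(BC_HEAD, strrep("A", 21), BC_TAIL, "GGGG"))
#' @export
extract_barcodes <- function(reads, head = BC_HEAD, tail = BC_TAIL,
                             expected_length = 21L) {
  if (!nzchar(head) || !nzchar(tail)) abort("anchors must be non-empty")
  if (expected_length < 1L) abort("`expected_length` must be >= 1")
  n <- length(reads)
  status <- rep("accepted", n)
  barcode <- rep(NA_character_, n)
  if (n > 0) {
    hpos <- regexpr(head, reads, fixed = TRUE)
    no_head <- hpos < 0L
    downstream <- substr(reads, hpos + nchar(head), .Machine$integer.max)
    tpos <- regexpr(tail, downstream, fixed = TRUE)
    no_tail <- !no_head & tpos < 0L
    insert <- substr(downstream, 1L, tpos - 1L)
    bad_len <- !no_head & !no_tail & nchar(insert) != expected_length
    uncalled <- !no_head & !no_tail & !bad_len &
      grepl("N", insert, fixed = TRUE)
    status[no_head] <- "rejected_no_head"
    status[no_tail] <- "rejected_no_tail"
    status[bad_len] <- "rejected_length"
    status[uncalled] <- "rejected_uncalled"
    ok <- status == "accepted"
    barcode[ok] <- insert[ok]
  }
  tibble(barcode = barcode,
         status = factor(status, levels = EXTRACT_STATUS))
}

#' Tally barcode counts for one FASTQ sample
#'
#' Applies [extract_barcodes()] to every read of a FASTQ file (plain or
#' gzip) and tallies accepted barcodes and QC categories. Memory for the
#' tally is bounded by the number of distinct barcodes.
#'
#' @param fastq_path Path to a FASTQ file.
#' @inheritParams extract_barcodes
#' @return A list of class `extraction_result`: `counts` (tibble `barcode`,
#'   `count`, sorted by decreasing count), `qc` (tibble `status`, `n` over
#'   all [EXTRACT_STATUS] levels), `total` reads and `discard_fraction`.
#' @export
count_sample <- function(fastq_path, head = BC_HEAD, tail = BC_TAIL,
                         expected_length = 21L) {
  reads <- read_fastq_sequences(fastq_path)
  res <- extract_barcodes(reads, head, tail, expected_length)
  qc <- res %>%
    count(.data$status, .drop = FALSE, name = "n") %>%
    as_tibble()
  counts <- res %>%
    filter(!is.na(.data$barcode)) %>%
    count(.data$barcode, name = "count") %>%
    arrange(dplyr::desc(.data$count), .data$barcode)
  total <- nrow(res)
  rejected <- total - sum(res$status == "accepted")
  structure(list(counts = counts, qc = qc, total = total,
                 discard_fraction = if (total > 0) rejected / total else 0),
            class = "extraction_result")
}

# strict single-pass reader for 4-line FASTQ records (plain or gzip);
# structural problems are reported with the index of the offending record
read_fastq_sequences <- function(fastq_path) {
  if (!file.exists(fastq_path)) {
    abort(sprintf("FASTQ file not found: %s", fastq_path))
  }
  lines <- readLines(fastq_path, warn = FALSE)
  n <- length(lines)
  if (n == 0) return(character(0))
  bad_rec <- function(i) {
    abort(sprintf("malformed FASTQ record %d in %s", i, fastq_path))
  }
  if (n %% 4 != 0) bad_rec(n %/% 4 + 1L)
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  seps <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  ok <- startsWith(ids, "@") & startsWith(seps, "+") &
    nchar(seqs) == nchar(quals)
  if (!all(ok)) bad_rec(which(!ok)[1])
  seqs
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %d reads, %d distinct barcodes, %.1f%% discarded\n",
              x$total, nrow(x$counts), 100 * x$discard_fraction))
  print(x$qc)
  invisible(x)
}

#' @rdname count_sample
#' @param x An `extraction_result`.
#' @param ... Unused.
#' @export
tidy.extraction_result <- function(x, ...) x$counts
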