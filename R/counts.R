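#' Merge technical sequencing replicates
#'
#' Sums read counts across the technical replicates of each well, collapsing
#' the `techrep` index; all other metadata columns are preserved. Per-well
#' totals after merging equal the summed per-techrep totals.
#'
#' @param counts Long count tibble with columns `barcode`, `count`,
#'   `condition`, `timepoint`, `well`, `techrep` (plus optional metadata).
#' @return Long tibble with one row per barcode x well, `sample_id` rebuilt
#'   as `condition_timepoint_wN`.
#' @export
merge_technical_replicates <- function(counts) {
  stopifnot_cols(counts, c("barcode", "count", "condition", "timepoint",
                           "well", "techrep"), "counts")
  counts %>%
    group_by(across(any_of(c("barcode", "cell_line", "condition",
                             "nk_genotype", "timepoint", "well")))) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(sample_id = sprintf("%s_%s_w%d", .data$condition,
                               .data$timepoint, .data$well))
}

#' Detection filter against the alone-arm reference samples
#'
#' Retains barcodes that are detected (>= 1 read) in each of the three
#' alone-condition wells at the reference timepoint and whose summed count
#' across those wells reaches `min_total` (default 9). `all_wells = FALSE`
#' relaxes detection to any well.
#'
#' @param counts Merged long count tibble (see
#'   [merge_technical_replicates()]).
#' @param reference_timepoint Timepoint of the alone-arm reference samples.
#' @param min_total Minimum summed count across the alone wells.
#' @param all_wells Require detection in every alone well (default) rather
#'   than any.
#' @param n_wells Expected number of alone wells (default 3).
#' @return Character vector of retained barcodes.
#' @export
detection_filter <- function(counts, reference_timepoint = "TP1",
                             min_total = 9, all_wells = TRUE, n_wells = 3) {
  stopifnot_cols(counts, c("barcode", "count", "condition", "timepoint",
                           "well"), "counts")
  ref <- filter(counts, .data$condition == "alone",
                .data$timepoint == reference_timepoint)
  wells <- unique(ref$well)
  if (length(wells) != n_wells) {
    abort(sprintf(
      "detection filter needs exactly %d alone wells at %s, found %d",
      n_wells, reference_timepoint, length(wells)))
  }
  per_bc <- ref %>%
    group_by(.data$barcode) %>%
    summarise(n_detected = sum(.data$count >= 1),
              total = sum(.data$count), .groups = "drop")
  detected <- if (all_wells) per_bc$n_detected == n_wells
              else per_bc$n_detected >= 1
  sort(per_bc$barcode[detected & per_bc$total >= min_total])
}

#' Per-sample size factors
#'
#' Computes a positive scale factor per sample making counts comparable
#' across sequencing depths. `method = "median-ratio"` uses the
#' median-of-ratios scheme: each barcode's geometric mean across samples
#' forms a pseudo-reference (barcodes with any zero are excluded) and the
#' factor is the median ratio of counts to that reference. If no barcode is
#' nonzero in every sample, the method falls back to library-size factors
#' with a warning. `method = "total"` uses library-size factors: per-sample
#' totals scaled to geometric mean 1.
#'
#' The median-of-ratios scheme assumes most barcodes are unchanged between
#' samples. Under strong immune selection a majority of clones is depleted
#' in the NK arm, the median ratio then tracks the depleted majority and
#' the factors absorb real signal; the pipeline therefore defaults to
#' library-size factors for the differential test (see the methods
#' vignette).
#'
#' @param counts Long count tibble (`barcode`, `sample_id`, `count`).
#' @param method `"median-ratio"` (default) or `"total"`.
#' @return Tibble `sample_id`, `size_factor` (all positive).
#' @examples
#' x <- tibble::tibble(barcode = rep(c("b1", "b2"), 2),
#'                     sample_id = rep(c("s1", "s2"), each = 2),
#'                     count = c(10, 20, 20, 40))
#' size_factors(x)
#' @export
size_factors <- function(counts, method = c("median-ratio", "total")) {
  method <- match.arg(method)
  m <- counts_to_matrix(counts)
  if (ncol(m) == 0) abort("no samples in `counts`")
  if (any(colSums(m) <= 0)) {
    abort("every sample must have at least one nonzero count")
  }
  sf <- if (method == "median-ratio") {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos)) {
      warn("no barcode is nonzero in every sample; falling back to library-size factors")
      total_factors(m)
    } else {
      ref <- apply(m[pos, , drop = FALSE], 1, geomean)
      apply(m[pos, , drop = FALSE], 2, function(col) median(col / ref))
    }
  } else {
    total_factors(m)
  }
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

total_factors <- function(m) {
  tot <- colSums(m)
  tot / geomean(tot)
}

#' Shifted log2 normalization
#'
#' Transforms counts to `log2(count / size_factor + 1)`, so zeros map to 0
#' and values increase monotonically with raw counts within a sample.
#'
#' @param counts Long count tibble (`barcode`, `sample_id`, `count`).
#' @param factors Size-factor tibble from [size_factors()]; computed with
#'   the given `method` when `NULL`.
#' @param method Passed to [size_factors()] when `factors` is `NULL`.
#' @return `counts` with columns `size_factor` and `log_norm` added.
#' @examples
#' x <- tibble::tibble(barcode = c("b1", "b2", "b3"), sample_id = "s1",
#'                     count = c(0, 1, 7))
#' shifted_log_normalize(x, tibble::tibble(sample_id = "s1", size_factor = 1))
#' @export
shifted_log_normalize <- function(counts, factors = NULL,
                                  method = c("median-ratio", "total")) {
  stopifnot_cols(counts, c("barcode", "sample_id", "count"), "counts")
  if (is.null(factors)) factors <- size_factors(counts, method = method)
  stopifnot_cols(factors, c("sample_id", "size_factor"), "factors")
  if (any(factors$size_factor <= 0)) abort("size factors must be positive")
  counts %>%
    left_join(factors, by = "sample_id") %>%
    mutate(log_norm = log2(.data$count / .data$size_factor + 1))
}
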