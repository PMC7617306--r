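#' Number of high-abundance wells
#'
#' A well is high when its value is at least `bar` doublings above the
#' shifted minimum across wells: `log2((x_i + 1) / (min(x) + 1)) >= bar`.
#' Used to detect secondary resistance, where a clone expands in a single
#' replicate well only.
#'
#' @param x Non-negative values across the NK-arm wells (the pipeline
#'   passes shifted-log2 normalized values).
#' @param bar Doubling threshold (default 1).
#' @return Integer count of high wells, in `0..length(x)`.
#' @examples
#' high_well_count(c(40, 0, 0))   # 1
#' high_well_count(c(40, 40, 0))  # 2
#' high_well_count(c(5, 5, 5))    # 0
#' @export
high_well_count <- function(x, bar = 1) {
  if (length(x) == 0) abort("`x` must be non-empty")
  sum(log2((x + 1) / (min(x) + 1)) >= bar)
}

#' Assign clone fates by the rule-based decision tree
#'
#' Evaluates the five-category decision rules in order, first match wins:
#'
#' 1. **primary resistant**: differentially abundant (`padj < padj_cut`)
#'    and increasing (`log2fc >= lfc_cut`);
#' 2. **eliminated**: differentially abundant and decreasing
#'    (`log2fc <= -lfc_cut`);
#' 3. **static**: low variability in both arms (`v_alone <= v_alone_cut`
#'    and `v_nk < v_nk_cut`);
#' 4. **secondary resistant**: low variability in the alone arm
#'    (`v_alone <= v_alone_cut`), high variability under NK pressure
#'    (`v_nk >= v_nk_cut`), and abundance high in exactly one of the
#'    replicate wells;
#' 5. **other**: none of the above.
#'
#' @param stats Per-barcode stats tibble from [clone_stats()] (columns
#'   `barcode`, `log2fc`, `padj`, `v_alone`, `v_nk`, `n_high_wells`).
#' @param padj_cut,lfc_cut,v_alone_cut,v_nk_cut Rule thresholds (defaults
#'   0.05, 1, 0.5, 1).
#' @return `stats` with columns `timepoint` (when known) and `category` (a
#'   factor over [FATE_LEVELS]) added; every barcode receives exactly one
#'   category.
#' @examples
#' classify_clones(tibble::tibble(
#'   barcode = c("b1", "b2"), log2fc = c(1.5, -2), padj = c(0.01, 0.01),
#'   v_alone = c(0.2, 0.2), v_nk = c(0.4, 0.3), n_high_wells = c(0, 0)))
#' @export
classify_clones <- function(stats, padj_cut = 0.05, lfc_cut = 1,
                            v_alone_cut = 0.5, v_nk_cut = 1) {
  stopifnot_cols(stats, c("barcode", "log2fc", "padj", "v_alone", "v_nk",
                          "n_high_wells"), "stats")
  needed <- stats[, c("log2fc", "padj", "v_alone", "v_nk", "n_high_wells")]
  bad <- !stats::complete.cases(needed)
  if (any(bad)) {
    abort(sprintf("missing statistics for barcode(s): %s",
                  paste(head(stats$barcode[bad], 5), collapse = ", ")))
  }
  category <- case_when(
    stats$padj < padj_cut & stats$log2fc >= lfc_cut ~ "primary_resistant",
    stats$padj < padj_cut & stats$log2fc <= -lfc_cut ~ "eliminated",
    stats$v_alone <= v_alone_cut & stats$v_nk < v_nk_cut ~ "static",
    stats$v_alone <= v_alone_cut & stats$v_nk >= v_nk_cut &
      stats$n_high_wells == 1 ~ "secondary_resistant",
    .default = "other")
  out <- mutate(stats, category = factor(category, levels = FATE_LEVELS))
  tp <- attr(stats, "timepoint", exact = TRUE)
  if (!is.null(tp) && !"timepoint" %in% names(out)) {
    out <- mutate(out, timepoint = tp, .before = "category")
  }
  out
}

#' Summarize fate-category proportions
#'
#' Counts clones per category (over all five levels, including empty ones)
#' and reports each category's proportion of the retained clones, plus a
#' renormalized proportion over the four named fates excluding `other`.
#' When `calls` spans several experiments (an `experiment` column), the
#' per-experiment proportions are pooled as mean and SD.
#'
#' @param calls Classified tibble from [classify_clones()] (column
#'   `category`; optional `timepoint` and `experiment` columns are used as
#'   grouping).
#' @return Tibble of per-category counts and proportions (summing to 1
#'   within each group), or pooled mean/SD proportions across experiments.
#' @export
summarize_fates <- function(calls) {
  stopifnot_cols(calls, "category", "calls")
  grouping <- intersect(c("experiment", "timepoint"), names(calls))
  per <- calls %>%
    mutate(category = factor(.data$category, levels = FATE_LEVELS)) %>%
    group_by(across(all_of(grouping))) %>%
    count(.data$category, .drop = FALSE, name = "n") %>%
    mutate(proportion = .data$n / sum(.data$n),
           proportion_excl_other =
             ifelse(.data$category == "other", NA_real_,
                    .data$n / sum(.data$n[.data$category != "other"]))) %>%
    ungroup()
  if (!"experiment" %in% grouping) return(per)
  per %>%
    group_by(across(all_of(c(setdiff(grouping, "experiment"), "category")))) %>%
    summarise(n_experiments = n(),
              mean_proportion = mean(.data$proportion),
              sd_proportion = stats::sd(.data$proportion),
              .groups = "drop")
}

#' Overlap of fate sets between two experiments
#'
#' For each category, compares the sets of barcodes assigned that fate in
#' two experiments: intersection and set-difference sizes and the Jaccard
#' index (0 when both sets are empty). Reproducibly fated clones
#' (eliminated, primary resistant, static) overlap strongly between
#' independent experiments, while secondary-resistant sets are largely
#' disjoint.
#'
#' @param calls1,calls2 Classified tibbles from [classify_clones()]
#'   (columns `barcode`, `category`).
#' @return Tibble per category: `n_both`, `n_only1`, `n_only2`, `jaccard`.
#' @export
overlap_fates <- function(calls1, calls2) {
  stopifnot_cols(calls1, c("barcode", "category"), "calls1")
  stopifnot_cols(calls2, c("barcode", "category"), "calls2")
  purrr::map(FATE_LEVELS, function(cat) {
    a <- unique(calls1$barcode[calls1$category == cat])
    b <- unique(calls2$barcode[calls2$category == cat])
    un <- union(a, b)
    tibble(category = cat,
           n_both = length(intersect(a, b)),
           n_only1 = length(setdiff(a, b)),
           n_only2 = length(setdiff(b, a)),
           jaccard = if (length(un) == 0) 0
                     else length(intersect(a, b)) / length(un))
  }) %>%
    bind_rows() %>%
    mutate(category = factor(.data$category, levels = FATE_LEVELS))
}

#' Order barcodes for display by hierarchical clustering
#'
#' Ward-linkage (`ward.D2`) agglomerative clustering on Euclidean distances
#' of the normalized abundance profiles; returns the leaf order, used to
#' arrange barcodes within each fate category in heatmaps. Fewer than two
#' profiles are returned as-is.
#'
#' @param x Numeric matrix (barcodes x samples, rownames = barcodes) or a
#'   long tibble with `barcode`, `sample_id` and a value column.
#' @param value Value column used when `x` is a tibble (default
#'   `"log_norm"`, falling back to `"count"`).
#' @return Character vector: the input barcodes in display order (a
#'   permutation of the input).
#' @export
order_barcodes <- function(x, value = NULL) {
  if (!is.matrix(x)) {
    if (is.null(value)) {
      value <- if ("log_norm" %in% names(x)) "log_norm" else "count"
    }
    x <- counts_to_matrix(x, value = value)
  }
  if (nrow(x) < 2) return(rownames(x))
  hc <- hclust(dist(x), method = "ward.D2")
  rownames(x)[hc$order]
}
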