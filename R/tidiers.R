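#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a differential-abundance result
#'
#' @param x A `clone_da` object from [diff_abundance()].
#' @param ... Unused.
#' @return The per-barcode result tibble.
#' @export
tidy.clone_da <- function(x, ...) x$result

#' @rdname tidy.clone_da
#' @export
glance.clone_da <- function(x, ...) {
  tibble(timepoint = x$timepoint,
         n_barcodes = nrow(x$result),
         n_nk = x$n_nk, n_alone = x$n_alone, df = x$df,
         sf_method = x$sf_method,
         n_significant = sum(x$result$padj < 0.05, na.rm = TRUE))
}

#' Tidy a pipeline run
#'
#' `tidy()` returns the per-clone fate calls joined with the generating
#' truth; `glance()` a one-row run summary.
#'
#' @param x A `clone_run` object from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.clone_run <- function(x, ...) {
  left_join(x$calls, x$truth[, c("barcode", "fate", "founder_abundance")],
            by = "barcode")
}

#' @rdname tidy.clone_run
#' @export
glance.clone_run <- function(x, ...) {
  tp2 <- filter(x$summary, .data$timepoint == max(x$summary$timepoint))
  props <- setNames(as.list(tp2$proportion),
                    paste0("prop_", tp2$category))
  div <- x$diversity %>%
    filter(.data$timepoint == max(.data$timepoint)) %>%
    group_by(.data$condition) %>%
    summarise(shannon = mean(.data$shannon), .groups = "drop")
  drop <- 1 - div$shannon[div$condition == "nk"] /
    div$shannon[div$condition == "alone"]
  as_tibble(c(list(n_clones = nrow(x$truth),
                   n_reference = nrow(x$reference),
                   n_retained = length(x$retained),
                   mean_discard = if (is.null(x$qc)) NA_real_ else
                     mean(distinct(x$qc, .data$sample_id,
                                   .data$discard_fraction)$discard_fraction),
                   shannon_drop = drop),
              props))
}
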