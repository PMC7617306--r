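#' Heatmap of normalized clone abundance by fate category
#'
#' Tile plot of shifted-log2 normalized abundance, barcodes grouped by fate
#' and ordered within each category by Ward (`ward.D2`) hierarchical
#' clustering, samples grouped by condition and timepoint.
#'
#' @param object A `clone_run` from [run_pipeline()].
#' @param timepoint Timepoint(s) to display (default both).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_run <- function(object, timepoint = NULL, ...) {
  calls <- filter(object$calls,
                  .data$timepoint == max(object$calls$timepoint))
  norm <- object$counts
  if (!is.null(timepoint)) {
    norm <- filter(norm, .data$timepoint %in% !!timepoint)
  }
  norm <- left_join(norm, calls[, c("barcode", "category")], by = "barcode")
  ordering <- norm %>%
    split(norm$category) %>%
    purrr::map(order_barcodes) %>%
    unlist(use.names = FALSE)
  norm <- mutate(norm, barcode = factor(.data$barcode, levels = ordering))
  ggplot2::ggplot(norm, ggplot2::aes(x = .data$sample_id, y = .data$barcode,
                                     fill = .data$log_norm)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(category ~ condition + timepoint,
                        scales = "free", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "norm.\nabundance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of fate-category proportions
#'
#' @param summary A [summarize_fates()] tibble (or a `clone_run`, whose
#'   summary is used).
#' @return A ggplot object.
#' @export
plot_fate_summary <- function(summary) {
  if (inherits(summary, "clone_run")) summary <- summary$summary
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$category, y = .data$proportion,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of retained clones") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1),
                   legend.position = "none")
  if ("timepoint" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~timepoint)
  }
  p
}

#' Bubble plot of secondary-resistant clones
#'
#' Shows, for each secondary-resistant clone, the normalized abundance per
#' replicate well in the alone arm at the early timepoint against the NK
#' arm at the late timepoint, visualising single-well expansion.
#'
#' @param run A `clone_run` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_secondary_bubbles <- function(run) {
  last_tp <- max(run$calls$timepoint)
  first_tp <- min(run$counts$timepoint)
  sec <- filter(run$calls, .data$timepoint == last_tp,
                .data$category == "secondary_resistant")
  dat <- run$counts %>%
    semi_join(sec, by = "barcode") %>%
    filter((.data$condition == "alone" & .data$timepoint == first_tp) |
             (.data$condition == "nk" & .data$timepoint == last_tp)) %>%
    mutate(panel = paste(.data$condition, .data$timepoint))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$well),
                                    y = .data$barcode,
                                    size = .data$log_norm,
                                    colour = .data$log_norm)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_colour_viridis_c(name = "norm.\nabundance") +
    ggplot2::scale_size_continuous(range = c(0, 6), guide = "none") +
    ggplot2::labs(x = "well", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Shannon diversity per sample
#'
#' @param diversity A [sample_diversity()] tibble (or a `clone_run`).
#' @return A ggplot object.
#' @export
plot_diversity <- function(diversity) {
  if (inherits(diversity, "clone_run")) diversity <- diversity$diversity
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$timepoint, y = .data$shannon,
                               colour = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3),
                        size = 2) +
    ggplot2::labs(y = "Shannon diversity (nats)", x = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
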