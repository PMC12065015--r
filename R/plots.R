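# ggplot2 views of the two result types: bar spectra (one panel per
# stratum, types 1-253 on the x axis) and the pairwise R^2 triangle.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar-spectrum plot of translocation frequency signatures
#'
#' One panel per stratum; the x axis runs over the 253 translocation
#' types in universe order, the y axis shows percentage frequencies.
#'
#' @param object A `trl_spectra` object.
#' @param labels Optional subset of strata to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trl_spectra <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(labels)) df <- dplyr::filter(df, .data$label %in% labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$pct)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1L,
      scales = "free_y") +
    ggplot2::labs(
      x = "translocation type (1–253, t(1;2) → t(X;22))",
      y = "frequency (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise R-squared matrix
#'
#' @param object A `trl_comparisons` tibble from [pairwise_comparisons()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trl_comparisons <- function(object, ...) {
  labs <- unique(c(object$label_a, object$label_b))
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      label_a = factor(.data$label_a, levels = labs),
      label_b = factor(.data$label_b, levels = labs)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_b, y = .data$label_a,
    fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r2)),
      size = 2.7, color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "R²") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}

#' Cutoff-sensitivity line plot
#'
#' R^2 against the characteristic-translocation cutoff, one line per
#' pair, for judging how strongly the exclusion threshold drives the
#' association.
#'
#' @param sensitivity A sensitivity table carrying `cutoff_pct`, `r2` and
#'   (optionally) `label_a`/`label_b` columns, as produced by
#'   [cutoff_sensitivity()] or [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_cutoff_sensitivity <- function(sensitivity) {
  df <- tibble::as_tibble(sensitivity)
  if (!all(c("label_a", "label_b") %in% names(df))) {
    df$label_a <- "a"
    df$label_b <- "b"
  }
  df$pair <- paste(df$label_a, "vs", df$label_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_pct, y = .data$r2,
    group = .data$pair, color = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "exclusion cutoff (%)", y = "R²",
      color = "pair") +
    ggplot2::theme_minimal()
}
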