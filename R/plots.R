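#' Manhattan-style detection-rate plot
#'
#' Plots per-SNP detection rates along the genome, with chromosomes in
#' alternating shades and an optional horizontal significance threshold.
#'
#' @param detections `nam_detection` or its `detections` tibble.
#' @param map Genetic map tibble.
#' @param threshold Optional DR threshold to draw.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(detections, map, threshold = NULL) {
  if (inherits(detections, "nam_detection")) {
    detections <- detections$detections
  }
  d <- dplyr::inner_join(detections, map, by = "snp_id") |>
    dplyr::arrange(.data$chrom, .data$pos_bp) |>
    dplyr::mutate(index = dplyr::row_number(),
                  chrom_f = factor(.data$chrom))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$dr,
                                       colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey25", "steelblue"),
                   length.out = dplyr::n_distinct(d$chrom))
    ) +
    ggplot2::labs(x = "SNP (map order)", y = "Detection rate (DR)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @rdname plot_manhattan
#' @param object,... `autoplot` arguments (`map`, `threshold` forwarded).
#' @export
autoplot.nam_detection <- function(object, map, threshold = NULL, ...) {
  plot_manhattan(object, map, threshold)
}

#' Box-Cox profile likelihood plot
#'
#' @param object A `nam_boxcox`.
#' @param ... Unused.
#' @return A ggplot object with the grid profile and the chosen lambda.
#' @export
autoplot.nam_boxcox <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$lambda, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = "dashed") +
    ggplot2::labs(x = expression(lambda), y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}

#' Variance-component bar plot
#'
#' @param object A `nam_varcomp`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nam_varcomp <- function(object, ...) {
  d <- dplyr::filter(object$components, .data$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "variance component",
      subtitle = sprintf("h2_SNP = %.3f", object$h2)
    ) +
    ggplot2::theme_minimal()
}

#' Family-effect heat map
#'
#' Tile plot of cumulated family-specific mQTL effects (mQTL x family).
#'
#' @param effects Tibble from [family_effects()].
#' @return A ggplot object.
#' @export
plot_family_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(.data$family_id, .data$mqtl_id,
                                        fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred") +
    ggplot2::labs(x = "family", y = "mQTL",
                  fill = "cumulated\neffect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
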