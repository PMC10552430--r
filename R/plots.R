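# ggplot2 views of the main result types.

#' Dotplot of collinear gene pairs
#'
#' Plots gene-gene pairs as segments in query-vs-target coordinate space,
#' one panel per chromosome pair, colored by orientation — the classic
#' synteny dotplot built from the collinear evidence table.
#'
#' @param pairs Collinear-pair tibble.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(pairs) {
  gg <- pairs |> filter(.data$pair_type == "gene-gene")
  ggplot2::ggplot(gg, ggplot2::aes(
    x = (.data$start_A + .data$end_A) / 2,
    y = (.data$start_B + .data$end_B) / 2,
    colour = ifelse(.data$inverted, "inverted", "forward")
  )) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::facet_grid(chrom_B ~ chrom_A, scales = "free") +
    ggplot2::scale_colour_manual(values = c(forward = "#2166ac", inverted = "#b2182b")) +
    ggplot2::labs(x = "target position (bp)", y = "query position (bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pan/core growth curves
#'
#' @param growth Tibble from [growth_curves()].
#' @return A ggplot object.
#' @export
plot_growth <- function(growth) {
  ggplot2::ggplot(growth, ggplot2::aes(.data$k, .data$mean, colour = .data$metric)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
                   fill = .data$metric),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "genomes sampled", y = "clusters",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Occupancy spectrum of a pangene set
#'
#' Bar chart of cluster counts per occupancy, filled by occupancy class.
#'
#' @param object A `pangene_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pangene_set <- function(object, ...) {
  occ <- cluster_occupancy(object) |>
    mutate(class = classify_occupancy(.data$occupancy, length(object$assemblies)))
  ggplot2::ggplot(occ, ggplot2::aes(factor(.data$occupancy), fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "occupancy (genomes)", y = "clusters", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
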