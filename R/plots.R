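#' Boxplots of trait variability across observers
#'
#' One boxplot with jittered observer values per karyomorphometric trait,
#' the standard display of how much each descriptor varies when different
#' people measure the same plate. Traits are faceted on free y scales since
#' THL is in length units while the others are percentages.
#'
#' @param study An `observer_study` table.
#' @param highlight Optional `observer_id`(s) drawn in red.
#' @return A ggplot object.
#' @export
plot_trait_boxplots <- function(study, highlight = NULL) {
  check_traits(study)
  long <- tibble::as_tibble(study) |>
    dplyr::select("observer_id", dplyr::all_of(karyo_traits)) |>
    tidyr::pivot_longer(dplyr::all_of(karyo_traits),
                        names_to = "trait", values_to = "value") |>
    dplyr::mutate(
      trait = factor(.data$trait, levels = karyo_traits),
      highlighted = .data$observer_id %in% (highlight %||% character())
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$highlighted),
                         width = 0.12, height = 0, size = 1.8,
                         show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::facet_wrap(~trait, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Inter-observer variability of karyotype traits") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Scatter plot of two traits across observers
#'
#' Per-observer values of one trait against another (THL vs M_CA by
#' default), annotated with the Pearson r and p of the pair.
#'
#' @inheritParams plot_trait_boxplots
#' @param trait_x,trait_y Trait names for the axes.
#' @return A ggplot object.
#' @export
plot_trait_scatter <- function(study, trait_x = "THL", trait_y = "M_CA",
                               highlight = NULL) {
  sc <- scatter_export(study, trait_x, trait_y, highlight = highlight)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = trait_x, y = trait_y,
      subtitle = sprintf("Pearson r = %.4f, two-sided p = %.5g",
                         attr(sc, "r"), attr(sc, "p"))
    ) +
    ggplot2::theme_bw()
}

#' @export
autoplot.observer_study <- function(object, highlight = NULL, ...) {
  plot_trait_boxplots(object, highlight = highlight)
}

#' @export
autoplot.karyo_cor <- function(object, ...) {
  td <- tidy(object)
  both <- dplyr::bind_rows(
    td,
    dplyr::rename(td, trait_x = "trait_y", trait_y = "trait_x")
  ) |>
    dplyr::mutate(
      trait_x = factor(.data$trait_x, levels = object$traits),
      trait_y = factor(.data$trait_y, levels = rev(object$traits))
    )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$trait_x, y = .data$trait_y,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("r=%.3f\np=%.3g", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
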