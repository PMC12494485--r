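# ggplot2 views of the main result types.

#' Plot a coverage track with detected islands
#'
#' Step plot of per-base depth for one contig, with island extents shaded
#' and the genome mean and drop threshold drawn as reference lines.
#'
#' @param coverage Coverage tibble from [compute_coverage()].
#' @param islands Optional island tibble from [detect_islands()].
#' @param contig Contig to plot (default: first in `coverage`).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, islands = NULL, contig = NULL) {
  check_columns(coverage, c("contig_id", "start", "end", "depth"), "coverage")
  if (is.null(contig)) contig <- coverage$contig_id[1]
  cov <- dplyr::filter(coverage, .data$contig_id == contig)
  p <- ggplot2::ggplot(cov) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$depth)) +
    ggplot2::labs(x = "position (bp)", y = "depth",
                  title = paste("Coverage:", contig)) +
    ggplot2::theme_minimal()
  if (!is.null(islands)) {
    isl <- dplyr::filter(islands, .data$contig_id == contig)
    if (nrow(isl) > 0) {
      p <- p +
        ggplot2::geom_rect(
          data = isl,
          ggplot2::aes(xmin = .data$start, xmax = .data$end,
                       ymin = -Inf, ymax = Inf, fill = .data$regime),
          alpha = 0.25, inherit.aes = FALSE
        ) +
        ggplot2::geom_hline(yintercept = isl$genome_mean[1], linetype = "dashed")
    }
  }
  p
}

#' Plot an eggNOG category profile
#'
#' @param profile Output of [summarize_categories()].
#' @return A ggplot object.
#' @export
plot_category_profile <- function(profile) {
  check_columns(profile, c("category", "percent"), "profile")
  lv <- profile$category
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$category, levels = lv),
                               y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "eggNOG category", y = "relative abundance (%)") +
    ggplot2::theme_minimal()
}

#' Plot the virus-host association spectrum
#'
#' @param spectrum Output of [association_spectrum()].
#' @return A ggplot object.
#' @export
plot_association_spectrum <- function(spectrum) {
  check_columns(spectrum, c("type", "percent"), "spectrum")
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = factor(.data$type, levels = spectrum$type),
                               y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of linked vOTUs") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
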