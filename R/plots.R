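#' Plot a genome tiling as stacked contig bars
#'
#' One horizontal bar per contig (ordered by length, longest first);
#' segment fill shows the assigned lineage, with unassigned positions in
#' light grey.
#'
#' @param tiling Segment tibble from [tile_genome()].
#' @param regions Optional region tibble; called foreign regions are
#'   outlined.
#' @return A ggplot object.
#' @export
plot_tiling <- function(tiling, regions = NULL) {
  ord <- tiling |>
    group_by(contig) |>
    summarise(len = max(end), .groups = "drop") |>
    arrange(desc(len))
  d <- tiling |>
    mutate(
      contig = factor(contig, levels = rev(ord$contig)),
      fill = ifelse(is.na(lineage), "no hit", lineage)
    )
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = start / 1000, xmax = end / 1000,
      ymin = as.integer(contig) - 0.4, ymax = as.integer(contig) + 0.4,
      fill = .data$fill
    )) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(d$contig)), labels = levels(d$contig)
    ) +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey85") +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "lineage") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    r <- regions |>
      mutate(contig = factor(contig, levels = rev(ord$contig)))
    p <- p + ggplot2::geom_rect(
      data = r,
      ggplot2::aes(
        xmin = start / 1000, xmax = end / 1000,
        ymin = as.integer(contig) - 0.45, ymax = as.integer(contig) + 0.45
      ),
      fill = NA, colour = "black", linewidth = 0.3
    )
  }
  p
}

#' Plot a coverage summary as a category bar chart
#'
#' @param coverage Tibble from [coverage_summary()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  d <- coverage |>
    mutate(label = ifelse(is.na(lineage), category,
                          paste0(category, ": ", lineage)))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, bp),
                                  y = bp / 1000, fill = category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "kb", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot donor tallies of nuclear HGT calls
#'
#' @param donor_summary Tibble from [summarize_donors()].
#' @return A ggplot object.
#' @export
plot_donor_summary <- function(donor_summary) {
  d <- donor_summary |>
    tidyr::pivot_longer(c(n_ogs, n_transcripts), names_to = "unit",
                        values_to = "n") |>
    mutate(unit = ifelse(.data$unit == "n_ogs", "orthogroups", "transcripts"))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(donor_family, -.data$n),
                                  y = .data$n, fill = .data$unit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "donor family", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot mito_scan
#' @export
autoplot.mito_scan <- function(object, ...) {
  plot_tiling(object$tiling, object$regions)
}

#' @method autoplot nuc_scan
#' @export
autoplot.nuc_scan <- function(object, ...) {
  plot_donor_summary(object$donor_summary)
}
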