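#' Plot an editing-outcome summary
#'
#' Bar chart of outcome-class fractions of total events.
#'
#' @param object An `editing_summary` from [summarize_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot editing_summary
#' @export
autoplot.editing_summary <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$class != "ambiguous" & !is.na(df$pct_of_total), , drop = FALSE]
  df$class <- factor(df$class, levels = JUNCTION_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = pct_of_total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of total events",
                  title = "Editing-outcome distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the AAV vector junction profile
#'
#' Histogram of vector-side breakpoint positions with ITR intervals shaded.
#'
#' @param object A `vector_profile` from [vector_junction_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vector_profile
#' @export
autoplot.vector_profile <- function(object, ...) {
  itr <- object$itr_intervals
  ggplot2::ggplot(object$histogram) +
    ggplot2::geom_rect(
      data = itr,
      ggplot2::aes(xmin = start, xmax = end, ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.25
    ) +
    ggplot2::geom_col(ggplot2::aes(x = bin_start, y = count),
                      width = diff(object$histogram$bin_start[1:2]),
                      just = 0, fill = "grey30") +
    ggplot2::labs(x = "vector position (bp)", y = "junctions",
                  title = sprintf("AAV junction profile (ITR fraction %.2f)",
                                  object$itr_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot discovered off-target support
#'
#' Lollipop chart of supporting molecule counts per discovered off-target
#' site, annotated with mismatch counts.
#'
#' @param sites Off-target site tibble from [discover_offtargets()].
#' @return A ggplot object.
#' @export
plot_offtarget_support <- function(sites) {
  stopifnot(is.data.frame(sites))
  df <- dplyr::mutate(sites,
                      label = sprintf("%s:%d (%dmm)", chrom, start, n_mismatches))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(label, -support),
                                   y = support)) +
    ggplot2::geom_segment(ggplot2::aes(xend = stats::reorder(label, -support),
                                       y = 0, yend = support),
                          colour = "grey60") +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "supporting molecules",
                  title = "Off-target translocation hotspots") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
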