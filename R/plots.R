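#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the stack size histogram, the per-site-type contact fractions, and the
#' distribution of simultaneous bound counts.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name gagstack-plots
NULL

#' @rdname gagstack-plots
#' @export
autoplot.stack_stats <- function(object, ...) {
  ggplot2::ggplot(object$size_histogram,
                  ggplot2::aes(x = factor(.data$size), y = .data$n_per_frame)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "stack size (molecules)",
                  y = "mean count per frame",
                  title = "Dye stack size distribution") +
    ggplot2::theme_minimal()
}

#' @rdname gagstack-plots
#' @export
autoplot.contact_table <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$fraction_pct))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$site_type, site_type_levels()),
    y = .data$fraction_pct)) +
    ggplot2::geom_col(fill = "#d95f02") +
    ggplot2::labs(x = NULL, y = "% of frames in contact",
                  title = sprintf("Contact fractions (cutoff %g Å)",
                                  attr(object, "cutoff"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname gagstack-plots
#' @export
autoplot.binding_summary <- function(object, ...) {
  ggplot2::ggplot(object$distribution,
                  ggplot2::aes(x = factor(.data$n_bound), y = .data$fraction)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::labs(x = "simultaneously bound dyes", y = "fraction of frames",
                  title = sprintf("Simultaneous binding (n_MB = %d, t = %.2f)",
                                  object$n_mb, object$t)) +
    ggplot2::theme_minimal()
}

#' Distance traces per dye and site type
#'
#' Line plot of the minimum dye-to-site distance over time, one facet per
#' dye, coloured by site type — the per-molecule view of the association/
#' dissociation dynamics.
#'
#' @param distances output of [mb_site_distances()].
#' @param cutoff optional horizontal reference line (Angstrom).
#' @return a ggplot object.
#' @export
plot_distance_traces <- function(distances, cutoff = 8) {
  df <- distances |>
    dplyr::summarise(distance = min(.data$distance),
                     .by = c("frame", "mb_id", "site_type"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$distance,
                                         colour = .data$site_type)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~mb_id) +
    ggplot2::labs(x = "frame", y = "min distance (Å)", colour = "site type") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    gg <- gg + ggplot2::geom_hline(yintercept = cutoff, linetype = 2)
  }
  gg
}
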