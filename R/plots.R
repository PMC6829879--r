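#' Plot methods for morphology results
#'
#' `autoplot()` on a single-image report shows the distribution of detected
#' line lengths with the 20/25/30/40-pixel bin edges marked. On a
#' timecourse it shows the detected line count per day, one line per
#' treatment group (the proliferation readout). [plot_length_bins()] shows
#' the length-bin composition as stacked bars (the tidy equivalent of
#' per-group pie charts), and [plot_length_scatter()] the per-line length
#' scatter by group and day.
#'
#' @param object A `morphology_report` or `morphology_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name morphology-plots
NULL

#' @rdname morphology-plots
#' @export
autoplot.morphology_report <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = 2.5, boundary = 20,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(20, 25, 30, 40),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "line length (px)", y = "lines",
                  title = object$image_id[1]) +
    ggplot2::theme_minimal()
}

#' @rdname morphology-plots
#' @export
autoplot.morphology_timecourse <- function(object, ...) {
  dat <- dplyr::summarise(
    dplyr::group_by(glance(object), .data$group, .data$day),
    n_lines = mean(.data$n_lines), .groups = "drop"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$n_lines,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "detected lines (mean per image)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @rdname morphology-plots
#' @param tc A `morphology_timecourse`.
#' @export
plot_length_bins <- function(tc) {
  dat <- tidyr::pivot_longer(
    glance(tc),
    cols = dplyr::all_of(c("pct_20_25", "pct_25_30", "pct_30_40",
                           "pct_gt40")),
    names_to = "bin", values_to = "pct"
  )
  dat$bin <- factor(dat$bin,
                    levels = c("pct_20_25", "pct_25_30", "pct_30_40",
                               "pct_gt40"),
                    labels = c("20-25", "25-30", "30-40", ">40"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$image_id, y = .data$pct,
                                    fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~ .data$group + .data$day, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of lines", fill = "length (px)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname morphology-plots
#' @export
plot_length_scatter <- function(tc) {
  dat <- tidy(tc)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$day),
                                    y = .data$length,
                                    colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "day", y = "line length (px)", colour = "group") +
    ggplot2::theme_minimal()
}
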