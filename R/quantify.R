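length_bin_breaks <- c(20, 25, 30, 40, Inf)
length_bin_labels <- c("20-25", "25-30", "30-40", ">40")

#' Summarize the morphology of one image
#'
#' Turns the polyline cells detected in one image into the morphological
#' readout: number of lines, their lengths (pixels), mean and sample SD,
#' and the percentage of lines in the length bins 20-25, 25-30, 30-40 and
#' >40 pixels. Bins are half-open `[lo, hi)` with a final `[40, Inf)`, so
#' every length >= 20 falls in exactly one bin and the percentages sum to
#' 100 when any line was detected.
#'
#' @param cells Output of [merge_fragments()], or a [polyline_length()]
#'   table; all cells must come from one image.
#' @param image_id Image label.
#' @param group Treatment group label (optional).
#' @param day Day index of the time series (optional).
#' @return A one-row `morphology_report` tibble: `image_id`, `group`,
#'   `day`, `n_lines`, `mean_length`, `sd_length`, `pct_20_25`,
#'   `pct_25_30`, `pct_30_40`, `pct_gt40`, and a `lengths` list-column.
#' @export
summarize_morphology <- function(cells, image_id = "image", group = NA,
                                 day = NA) {
  lengths <- if (nrow(cells) == 0) {
    numeric(0)
  } else if ("total_length" %in% names(cells)) {
    cells$total_length
  } else {
    polyline_length(cells)$total_length
  }
  if (any(lengths < 20)) {
    stop("polyline lengths below the 20-pixel floor (contract violation)")
  }
  n <- length(lengths)
  pct <- if (n > 0) {
    100 * as.numeric(table(cut(lengths, length_bin_breaks, right = FALSE,
                               labels = length_bin_labels))) / n
  } else {
    rep(0, 4)
  }
  out <- tibble::tibble(
    image_id = as.character(image_id),
    group = as.character(group),
    day = as.integer(day),
    n_lines = n,
    mean_length = if (n > 0) mean(lengths) else NA_real_,
    sd_length = if (n > 1) sd(lengths) else NA_real_,
    pct_20_25 = pct[1], pct_25_30 = pct[2],
    pct_30_40 = pct[3], pct_gt40 = pct[4],
    lengths = list(sort(lengths))
  )
  class(out) <- c("morphology_report", class(out))
  out
}

#' Assemble per-image reports into a timecourse table
#'
#' Binds one-row [summarize_morphology()] reports into a single tidy table
#' (one summary row per image) and numbers replicates within each
#' `(group, day)` stratum in `image_id` order. Use [tidy()] on the result
#' for the long per-line form suitable for plotting and external group
#' statistics.
#'
#' @param reports A list of `morphology_report` rows (or a tibble of bound
#'   reports).
#' @return A `morphology_timecourse` tibble.
#' @export
assemble_timecourse <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  out <- dplyr::bind_rows(reports)
  if (nrow(out) == 0) {
    out <- summarize_morphology(empty_segment_table())[0, ]
  }
  keys <- paste(out$group, out$day, out$image_id, sep = "\r")
  if (anyDuplicated(keys)) {
    stop("duplicate (group, day, image_id) keys (integrity error)")
  }
  out <- dplyr::arrange(out, .data$group, .data$day, .data$image_id)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$group, .data$day),
    replicate = dplyr::row_number(),
    .after = "day"
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("morphology_timecourse", setdiff(class(out),
                                                   "morphology_timecourse"))
  out
}

#' @rdname summarize_morphology
#' @param x A `morphology_report` or `morphology_timecourse`.
#' @param ... Unused.
#' @export
tidy.morphology_report <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), -dplyr::any_of(
      c("mean_length", "sd_length", "pct_20_25", "pct_25_30", "pct_30_40",
        "pct_gt40"))),
    cols = "lengths", keep_empty = FALSE
  ) |>
    dplyr::rename(length = "lengths")
}

#' @rdname summarize_morphology
#' @export
tidy.morphology_timecourse <- tidy.morphology_report

#' @rdname summarize_morphology
#' @export
glance.morphology_report <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"lengths")
}

#' @rdname summarize_morphology
#' @export
glance.morphology_timecourse <- glance.morphology_report
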