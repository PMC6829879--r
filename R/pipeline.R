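#' Pipeline configuration
#'
#' All tunables of the image pipeline in one flat list, with the package's
#' defaults: 3x3 median window; cube contrast enhancement; Canny at
#' sigma 1.5 with per-image hysteresis thresholds; Hough bins of 1 degree
#' by 1 pixel; 20-vote peak floor and 20-pixel minimum segment length;
#' duplicate removal below 15 pixels and 20 degrees; 5-pixel merge
#' tolerance. Serializes to a flat YAML file via [save_config()] /
#' [load_config()].
#'
#' @param median_kernel Median filter window (odd, pixels).
#' @param normalize Gray normalization, `"bitdepth"` or `"minmax"`.
#' @param canny_sigma Gaussian scale of the edge detector (pixels).
#' @param canny_low,canny_high Optional hysteresis fractions (see
#'   [canny_edges()]).
#' @param theta_step,rho_step Hough bin widths (radians, pixels).
#' @param min_votes Accumulator peak floor (votes).
#' @param peak_nhood Peak suppression window in bins, length 2.
#' @param min_length Minimum segment length (pixels).
#' @param max_gap Largest within-run gap when tracing segments (pixels).
#' @param lateral_tol Off-line tolerance when tracing segments (pixels).
#' @param dist_thresh,angle_thresh Duplicate-removal thresholds (pixels,
#'   degrees).
#' @param join_tol Fragment-merging endpoint tolerance (pixels).
#' @param overlay Write annotated overlay PNGs when an output directory is
#'   set.
#' @param debug_dump Write intermediate enhanced-gray and edge images.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(median_kernel = 3, normalize = "bitdepth",
                            canny_sigma = 1.5, canny_low = NULL,
                            canny_high = NULL, theta_step = pi / 180,
                            rho_step = 1, min_votes = 20,
                            peak_nhood = c(11, 11), min_length = 20,
                            max_gap = 3, lateral_tol = 2, dist_thresh = 15,
                            angle_thresh = 20, join_tol = 5,
                            overlay = FALSE, debug_dump = FALSE) {
  cfg <- list(
    median_kernel = median_kernel, normalize = normalize,
    canny_sigma = canny_sigma, canny_low = canny_low,
    canny_high = canny_high, theta_step = theta_step, rho_step = rho_step,
    min_votes = min_votes, peak_nhood = peak_nhood,
    min_length = min_length, max_gap = max_gap, lateral_tol = lateral_tol,
    dist_thresh = dist_thresh, angle_thresh = angle_thresh,
    join_tol = join_tol, overlay = overlay, debug_dump = debug_dump
  )
  stopifnot(
    cfg$min_length > 0, cfg$dist_thresh > 0, cfg$angle_thresh > 0,
    cfg$join_tol >= 0, cfg$rho_step > 0, cfg$theta_step > 0,
    cfg$min_votes >= 1
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline on one image
#'
#' Executes the three-stage chain on a single frame: preprocessing
#' (grayscale, median denoise, cube enhancement, Canny edges), Hough line
#' detection with the minimum-length floor, post-processing (duplicate
#' removal, fragment merging), and quantification. Optionally writes the
#' report (JSON), segment and cell tables (CSV), an annotated overlay PNG,
#' and intermediate debug images.
#'
#' @param path Image file path, or an in-memory gray matrix / RGB array in
#'   `[0, 1]`.
#' @param config A [pipeline_config()].
#' @param image_id Label for the report; defaults to the file name.
#' @param group,day Optional treatment / timepoint labels.
#' @param out_dir Optional output directory.
#' @return The `morphology_report` row, with the detected `segments` and
#'   merged `cells` tibbles and the `config` attached as attributes.
#' @export
run_image <- function(path, config = pipeline_config(), image_id = NULL,
                      group = NA, day = NA, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(path)) {
    img <- read_image(path)
    if (is.null(image_id)) image_id <- basename(path)
  } else {
    img <- path
    if (is.null(image_id)) image_id <- "image"
  }
  d <- dim(img)
  if (d[1] < 32 || d[2] < 32) {
    stop("image must be at least 32 x 32 pixels (dimensional error)")
  }

  gray <- to_grayscale(img, normalize = config$normalize)
  den <- median_denoise(gray, kernel = config$median_kernel)
  enh <- enhance_cube(den)
  edges <- canny_edges(enh, sigma = config$canny_sigma,
                       low = config$canny_low, high = config$canny_high)
  acc <- hough_accumulate(edges, theta_step = config$theta_step,
                          rho_step = config$rho_step)
  peaks <- find_peaks(acc, min_votes = config$min_votes,
                      nhood = config$peak_nhood)
  segs <- extract_segments(edges, peaks, min_length = config$min_length,
                           max_gap = config$max_gap,
                           lateral_tol = config$lateral_tol)
  kept <- remove_duplicates(segs, dist_thresh = config$dist_thresh,
                            angle_thresh = config$angle_thresh)
  cells <- merge_fragments(kept, join_tol = config$join_tol)
  report <- summarize_morphology(cells, image_id = image_id, group = group,
                                 day = day)
  attr(report, "segments") <- segs
  attr(report, "cells") <- cells
  attr(report, "config") <- config

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(image_id))
    rep_list <- c(
      as.list(glance(report)),
      list(lengths = report$lengths[[1]], config = unclass(config))
    )
    jsonlite::write_json(rep_list, file.path(out_dir,
                                             paste0(stem, "_report.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    utils::write.csv(dplyr::mutate(segs, image_id = image_id, .before = 1),
                     file.path(out_dir, paste0(stem, "_segments.csv")),
                     row.names = FALSE)
    utils::write.csv(dplyr::mutate(cells, image_id = image_id, .before = 1),
                     file.path(out_dir, paste0(stem, "_cells.csv")),
                     row.names = FALSE)
    if (isTRUE(config$overlay)) {
      write_image(render_overlay(img, cells),
                  file.path(out_dir, paste0(stem, "_overlay.png")))
    }
    if (isTRUE(config$debug_dump)) {
      write_image(enh, file.path(out_dir, paste0(stem, "_enhanced.png")))
      write_image(edges * 1, file.path(out_dir, paste0(stem, "_edges.png")))
    }
  }
  report
}

#' Run the pipeline over a group/day directory tree
#'
#' Walks `root/<group>/day<N>/*.{png,tif,tiff,jpg,jpeg}`, runs
#' [run_image()] on every frame, and assembles the per-image reports into a
#' timecourse table. Images that fail to process are logged as warnings and
#' skipped; the number of failures is attached as the `n_failed` attribute.
#'
#' @param root Root directory of the `group/dayN` layout.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (per-image outputs plus the
#'   assembled `timecourse.csv`).
#' @return A `morphology_timecourse` tibble.
#' @export
run_batch <- function(root, config = pipeline_config(), out_dir = NULL) {
  if (!dir.exists(root)) stop("root directory not found: ", root)
  files <- list.files(root, pattern = "\\.(png|tiff?|jpe?g)$",
                      ignore.case = TRUE, recursive = TRUE,
                      full.names = TRUE)
  rel <- strsplit(substring(files, nchar(root) + 2), "/")
  keep <- vapply(rel, function(p) {
    length(p) == 3 && grepl("^day[0-9]+$", p[2], ignore.case = TRUE)
  }, logical(1))
  files <- files[keep]
  rel <- rel[keep]
  if (length(files) == 0) {
    stop("no images found under ", root,
         " (expected <group>/day<N>/<image> layout)")
  }
  reports <- list()
  n_failed <- 0L
  for (k in seq_along(files)) {
    group <- rel[[k]][1]
    day <- as.integer(sub("^day", "", rel[[k]][2], ignore.case = TRUE))
    res <- tryCatch(
      run_image(files[k], config = config, image_id = rel[[k]][3],
                group = group, day = day, out_dir = out_dir),
      error = function(e) {
        warning("skipping ", files[k], ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(res)) n_failed <- n_failed + 1L else {
      reports[[length(reports) + 1]] <- res
    }
  }
  tc <- assemble_timecourse(reports)
  attr(tc, "n_failed") <- n_failed
  attr(tc, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(glance(tc), file.path(out_dir, "timecourse.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(tc), file.path(out_dir, "timecourse_lengths.csv"),
                     row.names = FALSE)
  }
  tc
}

#' Draw detected cells on an image
#'
#' Annotates a frame with its detections in the standard overlay
#' convention: each polyline cell in green (its length), the start point in
#' red, and the end point in yellow. The start is the spanning-chord
#' endpoint with the smaller `(y, x)`. Gray input is promoted to RGB;
#' passing zero cells returns the (promoted) input unchanged.
#'
#' @param img Gray matrix or `H x W x 3` array in `[0, 1]`.
#' @param cells Output of [merge_fragments()].
#' @return `H x W x 3` array with annotations.
#' @export
render_overlay <- function(img, cells) {
  if (length(dim(img)) == 2) {
    img <- array(img, dim = c(dim(img), 3))
  }
  h <- dim(img)[1]
  w <- dim(img)[2]
  set_px <- function(im, xs, ys, rgbv) {
    xs <- round(xs)
    ys <- round(ys)
    ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
    xs <- xs[ok]
    ys <- ys[ok]
    for (ch in 1:3) im[cbind(ys + 1, xs + 1, ch)] <- rgbv[ch]
    im
  }
  if (nrow(cells) == 0) return(img)
  for (k in seq_len(nrow(cells))) {
    n <- max(2, ceiling(cells$length[k]) * 2)
    t <- seq(0, 1, length.out = n)
    img <- set_px(img, cells$x1[k] + t * (cells$x2[k] - cells$x1[k]),
                  cells$y1[k] + t * (cells$y2[k] - cells$y1[k]),
                  c(0, 1, 0))
  }
  chords <- polyline_chords(cells)
  mark <- function(im, x, y, rgbv) {
    g <- expand.grid(dx = -1:1, dy = -1:1)
    set_px(im, x + g$dx, y + g$dy, rgbv)
  }
  for (k in seq_len(nrow(chords))) {
    p1 <- c(chords$x1[k], chords$y1[k])
    p2 <- c(chords$x2[k], chords$y2[k])
    swap <- (p2[2] < p1[2]) || (p2[2] == p1[2] && p2[1] < p1[1])
    start <- if (swap) p2 else p1
    end <- if (swap) p1 else p2
    img <- mark(img, start[1], start[2], c(1, 0, 0))
    img <- mark(img, end[1], end[2], c(1, 1, 0))
  }
  img
}
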