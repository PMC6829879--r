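#' Specify a synthetic microscopy scene
#'
#' Parameters of the seeded scene generator. The generator emulates the
#' imaging conditions of 200x brightfield frames of adherent epithelial
#' cells: adherent cells are darker than the culture medium (cytoplasm
#' transmits less light), detached floating cells are bright and rounded,
#' boundaries are blurred by the optics, illumination is not uniform across
#' the frame, and the sensor adds salt-and-pepper noise. Two adherent shape
#' classes are modeled: cobblestone (low-eccentricity blobs, the epithelial
#' phenotype) and elongated (slender capsules along a centerline, the
#' mesenchymal phenotype).
#'
#' @param size Image size in pixels, `c(height, width)` or a scalar.
#'   Default 320.
#' @param n_elongated,n_cobblestone,n_floating Object counts. Defaults 10,
#'   0, 0.
#' @param elongated_length Centerline length range in pixels. Default
#'   `c(50, 70)`.
#' @param elongated_aspect Length-to-width ratio of elongated cells
#'   (>= 3). Default 6.
#' @param cobblestone_diameter Diameter range of cobblestone cells in
#'   pixels. Default `c(15, 25)`.
#' @param floating_radius Radius range of floating cells in pixels.
#'   Default `c(4, 8)`.
#' @param cell_intensity,background_intensity,floating_intensity Gray
#'   levels in `[0, 1]`; must satisfy cell < background < floating.
#'   Defaults 0.45, 0.75, 0.95.
#' @param salt_pepper_rate Fraction of pixels hit by impulse noise.
#'   Default 0.002.
#' @param illumination_amplitude Relative amplitude of a linear
#'   illumination ramp across the frame. Default 0.1.
#' @param blur_sigma Gaussian blur scale in pixels. Default 1.
#' @param seed Mandatory integer seed; scenes are deterministic given the
#'   spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = 320, n_elongated = 10, n_cobblestone = 0,
                       n_floating = 0, elongated_length = c(50, 70),
                       elongated_aspect = 6,
                       cobblestone_diameter = c(15, 25),
                       floating_radius = c(4, 8),
                       cell_intensity = 0.45, background_intensity = 0.75,
                       floating_intensity = 0.95, salt_pepper_rate = 0.002,
                       illumination_amplitude = 0.1, blur_sigma = 1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory in a scene_spec")
  size <- rep(as.integer(size), length.out = 2)
  stopifnot(
    all(size >= 32),
    n_elongated >= 0, n_cobblestone >= 0, n_floating >= 0,
    elongated_aspect >= 3,
    cell_intensity < background_intensity,
    background_intensity < floating_intensity,
    cell_intensity >= 0, floating_intensity <= 1,
    salt_pepper_rate >= 0, salt_pepper_rate < 1,
    blur_sigma >= 0
  )
  structure(
    list(
      size = size, n_elongated = n_elongated,
      n_cobblestone = n_cobblestone, n_floating = n_floating,
      elongated_length = sort(elongated_length),
      elongated_aspect = elongated_aspect,
      cobblestone_diameter = sort(cobblestone_diameter),
      floating_radius = sort(floating_radius),
      cell_intensity = cell_intensity,
      background_intensity = background_intensity,
      floating_intensity = floating_intensity,
      salt_pepper_rate = salt_pepper_rate,
      illumination_amplitude = illumination_amplitude,
      blur_sigma = blur_sigma, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the objects described by a [scene_spec()] onto a uniform medium:
#' elongated cells as dark capsules along random centerlines, cobblestone
#' cells as dark low-eccentricity ellipses, floating cells as bright discs.
#' An illumination ramp, Gaussian blur, and salt-and-pepper noise are then
#' applied. Placement is rejection-sampled so that adherent cells keep
#' enough clearance that distinct neighbors are not confused for duplicate
#' markings of one cell; running out of attempts raises a placement error.
#' Deterministic for a fixed seed.
#'
#' @param spec A [scene_spec()].
#' @return List of class `synthetic_scene`: `image` (`H x W x 3` array in
#'   `[0, 1]`), `truth` (tibble: `id`, `class`, `x1, y1, x2, y2` centerline
#'   for elongated cells, `cx, cy, radius`, `length`), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    h <- spec$size[1]
    w <- spec$size[2]
    img <- matrix(spec$background_intensity, h, w)
    truth <- place_objects(spec)
    for (k in seq_len(nrow(truth))) {
      ob <- truth[k, ]
      img <- switch(
        ob$class,
        elongated = paint_capsule(img, ob$x1, ob$y1, ob$x2, ob$y2,
                                  ob$radius, spec$cell_intensity),
        cobblestone = paint_ellipse(img, ob$cx, ob$cy, ob$a, ob$b, ob$phi,
                                    spec$cell_intensity),
        floating = paint_disc(img, ob$cx, ob$cy, ob$radius,
                              spec$floating_intensity)
      )
    }
    # non-uniform illumination: linear ramp along x
    if (spec$illumination_amplitude != 0) {
      ramp <- 1 + spec$illumination_amplitude *
        (matrix(seq_len(w) - 1, h, w, byrow = TRUE) / (w - 1) - 0.5)
      img <- img * ramp
    }
    if (spec$blur_sigma > 0) img <- gaussian_smooth(img, spec$blur_sigma)
    n_sp <- round(spec$salt_pepper_rate * h * w)
    if (n_sp > 0) {
      at <- sample.int(h * w, n_sp)
      img[at] <- ifelse(runif(n_sp) < 0.5, 0, 1)
    }
    img <- pmin(pmax(img, 0), 1)
    rgb <- array(img, dim = c(h, w, 3))
    structure(
      list(image = rgb, truth = truth[, c("id", "class", "x1", "y1", "x2",
                                          "y2", "cx", "cy", "radius",
                                          "length")],
           spec = spec),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> ", paste(dim(x$image)[1:2], collapse = " x "),
      " px; ", nrow(x$truth), " objects (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

# rejection-sampled object placement with clearance constraints
place_objects <- function(spec, max_attempts = 2000) {
  h <- spec$size[1]
  w <- spec$size[2]
  rows <- list()
  # clearance between adherent cells keeps the 15-px duplicate rule from
  # deleting a true neighbor's line
  clearance <- 16
  seg_dist_to_placed <- function(x1, y1, x2, y2) {
    if (length(rows) == 0) return(Inf)
    pl <- dplyr::bind_rows(rows)
    min(seg_pair_min_dist(x1, y1, x2, y2,
                          pl$x1, pl$y1, pl$x2, pl$y2) - pl$radius)
  }
  add <- function(class, n, sampler) {
    for (k in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- sampler()
        margin <- cand$radius + 3
        inside <- all(c(cand$x1, cand$x2) >= margin) &&
          all(c(cand$x1, cand$x2) <= w - 1 - margin) &&
          all(c(cand$y1, cand$y2) >= margin) &&
          all(c(cand$y1, cand$y2) <= h - 1 - margin)
        if (!inside) next
        gap <- seg_dist_to_placed(cand$x1, cand$y1, cand$x2, cand$y2) -
          cand$radius
        if (gap < clearance) next
        rows[[length(rows) + 1]] <<- dplyr::mutate(cand, class = class)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("placement error: could not place ", class, " object ", k,
             " within ", max_attempts, " attempts")
      }
    }
  }
  add("elongated", spec$n_elongated, function() {
    len <- runif(1, spec$elongated_length[1], spec$elongated_length[2])
    r <- len / spec$elongated_aspect / 2
    ang <- runif(1, 0, pi)
    cx <- runif(1, 0, w - 1)
    cy <- runif(1, 0, h - 1)
    dx <- cos(ang) * len / 2
    dy <- sin(ang) * len / 2
    tibble::tibble(x1 = cx - dx, y1 = cy - dy, x2 = cx + dx, y2 = cy + dy,
                   cx = cx, cy = cy, radius = r, length = len,
                   a = NA_real_, b = NA_real_, phi = ang)
  })
  add("cobblestone", spec$n_cobblestone, function() {
    d <- runif(1, spec$cobblestone_diameter[1], spec$cobblestone_diameter[2])
    aspect <- runif(1, 1, 1.5)
    cx <- runif(1, 0, w - 1)
    cy <- runif(1, 0, h - 1)
    tibble::tibble(x1 = cx, y1 = cy, x2 = cx, y2 = cy, cx = cx, cy = cy,
                   radius = d / 2, length = NA_real_,
                   a = d / 2, b = d / 2 / aspect, phi = runif(1, 0, pi))
  })
  add("floating", spec$n_floating, function() {
    r <- runif(1, spec$floating_radius[1], spec$floating_radius[2])
    cx <- runif(1, 0, w - 1)
    cy <- runif(1, 0, h - 1)
    tibble::tibble(x1 = cx, y1 = cy, x2 = cx, y2 = cy, cx = cx, cy = cy,
                   radius = r, length = NA_real_,
                   a = NA_real_, b = NA_real_, phi = NA_real_)
  })
  empty <- tibble::tibble(
    x1 = double(), y1 = double(), x2 = double(), y2 = double(),
    cx = double(), cy = double(), radius = double(), length = double(),
    a = double(), b = double(), phi = double(), class = character()
  )
  out <- dplyr::bind_rows(c(list(empty), rows))
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

# --- painters (bounding-box restricted, coordinates zero-based) -------------

pixel_grid <- function(img, x_lo, x_hi, y_lo, y_hi) {
  h <- nrow(img)
  w <- ncol(img)
  rows <- max(1, floor(y_lo) + 1):min(h, ceiling(y_hi) + 1)
  cols <- max(1, floor(x_lo) + 1):min(w, ceiling(x_hi) + 1)
  list(rows = rows, cols = cols,
       x = matrix(cols - 1, length(rows), length(cols), byrow = TRUE),
       y = matrix(rows - 1, length(rows), length(cols)))
}

paint_capsule <- function(img, x1, y1, x2, y2, r, value) {
  g <- pixel_grid(img, min(x1, x2) - r, max(x1, x2) + r,
                  min(y1, y2) - r, max(y1, y2) + r)
  d <- point_seg_dist(as.vector(g$x), as.vector(g$y), x1, y1, x2, y2)
  sub <- img[g$rows, g$cols]
  sub[d <= r] <- value
  img[g$rows, g$cols] <- sub
  img
}

paint_ellipse <- function(img, cx, cy, a, b, phi, value) {
  g <- pixel_grid(img, cx - a, cx + a, cy - a, cy + a)
  dx <- as.vector(g$x) - cx
  dy <- as.vector(g$y) - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[g$rows, g$cols]
  sub[inside] <- value
  img[g$rows, g$cols] <- sub
  img
}

paint_disc <- function(img, cx, cy, r, value) {
  paint_ellipse(img, cx, cy, r, r, 0, value)
}

# run code under a temporary RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Score detections against scene ground truth
#'
#' Greedy one-to-one matching of detected polyline cells to the elongated
#' ground-truth centerlines. Each detected cell is reduced to its spanning
#' chord (the farthest pair among its segment endpoints); a
#' (detection, truth) pair is a candidate when the chord midpoints lie
#' within `match_dist` and the directions within `match_angle`. Candidates
#' are accepted in order of increasing midpoint distance, one match per
#' side.
#'
#' @param cells Output of [merge_fragments()] (segments with `cell_id`).
#' @param truth Ground-truth tibble from [generate_scene()].
#' @param match_dist Midpoint distance gate in pixels. Default 15.
#' @param match_angle Direction gate in degrees. Default 20.
#' @return One-row tibble: `n_detected`, `n_truth`, `n_matched`,
#'   `precision`, `recall`, `count_error` (relative), `mean_length_error`
#'   (mean relative error over matches), `total_cost` (summed matched
#'   midpoint distances), and a `matches` list-column.
#' @export
evaluate_recovery <- function(cells, truth, match_dist = 15,
                              match_angle = 20) {
  det <- polyline_chords(cells)
  tru <- truth[truth$class == "elongated", , drop = FALSE]
  nd <- nrow(det)
  nt <- nrow(tru)
  cand <- NULL
  if (nd > 0 && nt > 0) {
    cand <- tidyr::expand_grid(di = seq_len(nd), ti = seq_len(nt))
    mdx <- (det$x1[cand$di] + det$x2[cand$di]) / 2 -
      (tru$x1[cand$ti] + tru$x2[cand$ti]) / 2
    mdy <- (det$y1[cand$di] + det$y2[cand$di]) / 2 -
      (tru$y1[cand$ti] + tru$y2[cand$ti]) / 2
    cand$cost <- sqrt(mdx^2 + mdy^2)
    cand$angle <- seg_pair_angle(det$x1[cand$di], det$y1[cand$di],
                                 det$x2[cand$di], det$y2[cand$di],
                                 tru$x1[cand$ti], tru$y1[cand$ti],
                                 tru$x2[cand$ti], tru$y2[cand$ti])
    cand <- cand[cand$cost <= match_dist & cand$angle <= match_angle, ]
    cand <- cand[order(cand$cost, cand$di, cand$ti), ]
  }
  used_d <- logical(nd)
  used_t <- logical(nt)
  matches <- list()
  for (r in seq_len(NROW(cand))) {
    di <- cand$di[r]
    ti <- cand$ti[r]
    if (used_d[di] || used_t[ti]) next
    used_d[di] <- TRUE
    used_t[ti] <- TRUE
    matches[[length(matches) + 1]] <- tibble::tibble(
      cell_id = det$cell_id[di], truth_id = tru$id[ti],
      cost = cand$cost[r],
      rel_length_error = abs(det$total_length[di] - tru$length[ti]) /
        tru$length[ti]
    )
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(cell_id = integer(), truth_id = integer(),
                   cost = double(), rel_length_error = double())
  nm <- nrow(matches)
  tibble::tibble(
    n_detected = nd, n_truth = nt, n_matched = nm,
    precision = if (nd > 0) nm / nd else NA_real_,
    recall = if (nt > 0) nm / nt else NA_real_,
    count_error = if (nt > 0) abs(nd - nt) / nt else NA_real_,
    mean_length_error = if (nm > 0) mean(matches$rel_length_error)
    else NA_real_,
    total_cost = sum(matches$cost),
    matches = list(matches)
  )
}

# reduce each polyline cell to its spanning chord and total length
polyline_chords <- function(cells) {
  if (nrow(cells) == 0) {
    return(tibble::tibble(cell_id = integer(), x1 = double(), y1 = double(),
                          x2 = double(), y2 = double(),
                          total_length = double()))
  }
  stopifnot("cell_id" %in% names(cells))
  split(cells, cells$cell_id) |>
    purrr::map(function(g) {
      px <- c(g$x1, g$x2)
      py <- c(g$y1, g$y2)
      dd <- outer(px, px, "-")^2 + outer(py, py, "-")^2
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      tibble::tibble(cell_id = g$cell_id[1],
                     x1 = px[ij[1]], y1 = py[ij[1]],
                     x2 = px[ij[2]], y2 = py[ij[2]],
                     total_length = sum(g$length))
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$cell_id)
}
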