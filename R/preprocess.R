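#' Read a microscopy frame from disk
#'
#' Reads PNG, TIFF or JPEG (8- or 16-bit, gray or RGB) into the matrix/array
#' convention used throughout the package: a numeric `H x W` matrix for gray
#' images or an `H x W x 3` array for color images, intensities in `[0, 1]`,
#' rows running top to bottom.
#'
#' @param path Path to an image file.
#' @return Numeric matrix (gray) or 3-d array (RGB), values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e))
  )
  dat <- EBImage::imageData(img)
  # EBImage stores x (width) first; transpose to rows = y, cols = x
  if (length(dim(dat)) == 2) {
    out <- t(dat)
  } else {
    nc <- dim(dat)[3]
    if (nc == 1) {
      out <- t(dat[, , 1])
    } else {
      out <- aperm(dat[, , seq_len(min(nc, 3)), drop = FALSE], c(2, 1, 3))
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Write a gray matrix or RGB array to PNG
#'
#' @param img `H x W` matrix or `H x W x 3` array with values in `[0, 1]`.
#' @param path Output file path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  dat <- if (length(dim(img)) == 2) t(img) else aperm(img, c(2, 1, 3))
  cs <- if (length(dim(img)) == 2) "Gray" else "Color"
  EBImage::writeImage(EBImage::Image(dat, colormode = cs), path, type = "png")
  invisible(path)
}

#' Convert an RGB frame to a normalized gray image
#'
#' Combines channels with ITU-R BT.601 luminance weights (0.299, 0.587,
#' 0.114) and rescales to `[0, 1]`. Equal-channel pixels map to their common
#' value regardless of the weights. Integer-valued input in `[0, 255]` is
#' divided by 255 (fixed bit-depth normalization, so frames of a time series
#' share one scale); input already in `[0, 1]` passes through unscaled.
#' Single-channel input is accepted and only normalized.
#'
#' @param img `H x W x 3` array, or `H x W` matrix for already-gray input.
#' @param normalize `"bitdepth"` (default; divide by 255 when values exceed
#'   1) or `"minmax"` (per-image min-max rescaling).
#' @return Numeric `H x W` matrix with values in `[0, 1]`.
#' @export
to_grayscale <- function(img, normalize = c("bitdepth", "minmax")) {
  normalize <- match.arg(normalize)
  d <- dim(img)
  if (length(d) == 3) {
    if (d[3] != 3) {
      stop("expected 3 channels, got ", d[3], " (dimensional error)")
    }
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else if (length(d) == 2) {
    gray <- img
  } else {
    stop("expected an H x W x 3 array or H x W matrix (dimensional error)")
  }
  if (normalize == "minmax") {
    rng <- range(gray)
    gray <- if (diff(rng) > 0) (gray - rng[1]) / diff(rng) else gray * 0
  } else if (max(gray) > 1) {
    gray <- gray / 255
  }
  pmin(pmax(gray, 0), 1)
}

#' Median-filter a gray image
#'
#' Replaces each pixel by the median of its `kernel x kernel` neighborhood
#' (borders replicated), removing salt-and-pepper noise while preserving
#' sharp cell boundaries.
#'
#' @param img Numeric `H x W` matrix in `[0, 1]`.
#' @param kernel Odd window size in pixels, `>= 3`. Default 3.
#' @return Filtered matrix, same dimensions.
#' @export
median_denoise <- function(img, kernel = 3) {
  if (length(kernel) != 1 || is.na(kernel) || kernel < 3 ||
      kernel %% 2 != 1) {
    stop("kernel must be an odd integer >= 3 (parameter error)")
  }
  stopifnot(is.matrix(img))
  median_filter_cpp(img, as.integer(kernel))
}

#' Cube contrast enhancement
#'
#' Applies `F(i,j) = G(i,j)^3` elementwise. The cube has a shallow slope at
#' low intensities, so the relatively dark cells are stretched further from
#' the brighter culture medium, sharpening boundary contrast. Strictly
#' monotone on `(0, 1)` with `F <= G`.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @return Enhanced matrix, values in `[0, 1]`.
#' @export
enhance_cube <- function(img) {
  if (any(img < 0 | img > 1)) {
    stop("intensities must lie in [0, 1] (contract violation)")
  }
  img^3
}

#' Canny edge detection
#'
#' Binary boundary map via the classic chain: Gaussian-derivative gradient,
#' non-maximum suppression along the gradient direction, and hysteresis
#' thresholding with 8-connected linking.
#'
#' When `low`/`high` are `NULL` the hysteresis thresholds are derived from
#' the image's gradient-magnitude distribution: the high threshold is the
#' Otsu split of the magnitude histogram (which separates the boundary mode
#' from the background mode even when non-uniform illumination gives every
#' background pixel a small nonzero gradient) and the low threshold is 0.4
#' times the high one. Because these thresholds are relative, they would
#' adapt down to noise level on a featureless frame, so the derived high
#' threshold is floored at `min_grad` (an absolute gradient in normalized
#' intensity units; boundary gradients of adherent cells are an order of
#' magnitude above it). Explicit `low < high` in `[0, 1]` are interpreted
#' as fractions of the maximum gradient magnitude.
#'
#' @param img Numeric `H x W` gray matrix.
#' @param sigma Gaussian smoothing scale in pixels (> 0). Default 1.5.
#' @param low,high Optional hysteresis fractions, `0 <= low < high <= 1`.
#' @param min_grad Absolute floor for the derived high threshold, in
#'   intensity units per pixel. Default 0.01.
#' @return Logical `H x W` matrix; `TRUE` marks boundary pixels.
#' @export
canny_edges <- function(img, sigma = 1.5, low = NULL, high = NULL,
                        min_grad = 0.01) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) stop("sigma must be > 0 (parameter error)")
  if (!is.null(low) || !is.null(high)) {
    if (is.null(low) || is.null(high) || low < 0 || high > 1 ||
        low >= high) {
      stop("need 0 <= low < high <= 1 (parameter error)")
    }
  }

  sm <- gaussian_smooth(img, sigma)
  gx <- sobel_x(sm)
  gy <- sobel_y(sm)
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag < 1e-12)) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }

  nms <- nonmax_suppress(mag, gx, gy)

  if (is.null(high)) {
    mx <- max(mag)
    high_val <- EBImage::otsu(EBImage::Image(mag / mx), range = c(0, 1)) * mx
    high_val <- max(high_val, min_grad)
    low_val <- 0.4 * high_val
  } else {
    high_val <- high * max(mag)
    low_val <- low * max(mag)
  }
  weak <- nms & (mag >= low_val)
  strong <- nms & (mag >= high_val)
  hysteresis_cpp(weak, strong)
}

# --- internal raster helpers -------------------------------------------------

# shift a matrix by (di, dj) with replicated borders
shift_replicate <- function(m, di, dj) {
  h <- nrow(m)
  w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - di, 1), h)
  ci <- pmin(pmax(seq_len(w) - dj, 1), w)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian convolution, replicate borders
gaussian_smooth <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (d in seq(-r, r)) out <- out + k[d + r + 1] * shift_replicate(img, d, 0)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (d in seq(-r, r)) out2 <- out2 + k[d + r + 1] * shift_replicate(out, 0, d)
  out2
}

# Sobel derivative along x (columns); y is rows, increasing downward
sobel_x <- function(m) {
  gx <- shift_replicate(m, 0, -1) - shift_replicate(m, 0, 1)
  (2 * gx +
     (shift_replicate(m, -1, -1) - shift_replicate(m, -1, 1)) +
     (shift_replicate(m, 1, -1) - shift_replicate(m, 1, 1))) / 8
}

sobel_y <- function(m) {
  gy <- shift_replicate(m, -1, 0) - shift_replicate(m, 1, 0)
  (2 * gy +
     (shift_replicate(m, -1, -1) - shift_replicate(m, 1, -1)) +
     (shift_replicate(m, -1, 1) - shift_replicate(m, 1, 1))) / 8
}

# keep local maxima of |grad| along the gradient direction, with linear
# interpolation of the magnitude at the two off-grid sample points
nonmax_suppress <- function(mag, gx, gy) {
  h <- nrow(mag)
  w <- ncol(mag)
  i <- as.vector(row(mag))
  j <- as.vector(col(mag))
  m <- as.vector(mag)
  ax <- abs(as.vector(gx))
  ay <- abs(as.vector(gy))
  sx <- sign(as.vector(gx))
  sy <- sign(as.vector(gy))

  at <- function(di, dj) {
    ii <- pmin(pmax(i + di, 1), h)
    jj <- pmin(pmax(j + dj, 1), w)
    m[ii + (jj - 1) * h]
  }
  horiz <- ax >= ay  # gradient closer to the x axis
  wgt <- ifelse(horiz, ifelse(ax > 0, ay / ax, 0),
                ifelse(ay > 0, ax / ay, 0))
  ds_i <- ifelse(horiz, 0, sy)  # straight sample offset
  ds_j <- ifelse(horiz, sx, 0)
  n1 <- (1 - wgt) * at(ds_i, ds_j) + wgt * at(sy, sx)
  n2 <- (1 - wgt) * at(-ds_i, -ds_j) + wgt * at(-sy, -sx)
  keep <- m >= n1 & m >= n2 & m > 1e-12
  matrix(keep, h, w)
}
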