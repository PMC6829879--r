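#' Hough transform of an edge image
#'
#' Maps every edge pixel `(x, y)` (zero-based, x = column, y = row) to votes
#' in the discretized normal-parameter plane: for each angle bin `theta` in
#' `[0, pi)`, one vote is added at the distance bin nearest
#' `rho = x cos(theta) + y sin(theta)`. Collinear pixels vote the same
#' `(theta, rho)` bin, so straight cell boundaries appear as accumulator
#' peaks.
#'
#' @param edges Logical `H x W` matrix (`TRUE` = boundary pixel).
#' @param theta_step Angular bin width in radians. Default `pi/180` (1 degree).
#' @param rho_step Distance bin width in pixels (> 0). Default 1.
#' @return A `hough_accumulator`: list with `votes` (`n_theta x n_rho`
#'   integer matrix), `theta` (bin centers, radians), `rho` (bin centers,
#'   pixels, spanning `[-D, D]` with `D` the image diagonal), and `dim`
#'   (source image dimensions).
#' @export
hough_accumulate <- function(edges, theta_step = pi / 180, rho_step = 1) {
  stopifnot(is.matrix(edges))
  if (rho_step <= 0) stop("rho_step must be > 0 (parameter error)")
  n_theta <- floor(pi / theta_step + 1e-9)
  if (n_theta < 1) stop("theta_step admits no theta bin (parameter error)")
  theta <- (seq_len(n_theta) - 1) * theta_step
  h <- nrow(edges)
  w <- ncol(edges)
  d <- ceiling(sqrt((h - 1)^2 + (w - 1)^2))
  rho <- seq(-d, d, by = rho_step)
  pts <- which(edges != 0, arr.ind = TRUE)
  x <- as.numeric(pts[, 2] - 1)
  y <- as.numeric(pts[, 1] - 1)
  votes <- hough_accumulate_cpp(x, y, theta, d, rho_step, length(rho))
  structure(
    list(votes = votes, theta = theta, rho = rho, dim = c(h, w)),
    class = "hough_accumulator"
  )
}

#' @export
print.hough_accumulator <- function(x, ...) {
  cat("<hough_accumulator> ", length(x$theta), " theta bins x ",
      length(x$rho), " rho bins, ", sum(x$votes), " votes\n", sep = "")
  invisible(x)
}

#' Find peaks in a Hough accumulator
#'
#' Greedy non-maximum suppression: repeatedly takes the largest remaining
#' vote count (ties broken toward the lower theta bin, then the lower rho
#' bin), records it, and suppresses the surrounding `nhood` window. The
#' window wraps at `theta = pi` with `rho` negated, so the two parameter
#' images of one undirected line are suppressed together.
#'
#' @param acc A `hough_accumulator`.
#' @param min_votes Minimum vote count for a peak (>= 1).
#' @param nhood Suppression window `(theta bins, rho bins)`; odd integers.
#'   Default `c(11, 11)`.
#' @param max_peaks Optional cap on the number of peaks returned.
#' @return Tibble with columns `theta`, `rho`, `votes`, in descending vote
#'   order. Zero rows when nothing reaches `min_votes`.
#' @export
find_peaks <- function(acc, min_votes = 20, nhood = c(11, 11),
                       max_peaks = Inf) {
  stopifnot(inherits(acc, "hough_accumulator"))
  if (min_votes < 1) stop("min_votes must be >= 1 (parameter error)")
  nhood <- rep(as.integer(nhood), length.out = 2)
  ht <- nhood[1] %/% 2
  hr <- nhood[2] %/% 2
  v <- acc$votes
  nt <- nrow(v)
  nr <- ncol(v)
  out <- list()
  while (length(out) < max_peaks) {
    m <- max(v)
    if (m < min_votes) break
    idx <- which(v == m)
    ti <- (idx - 1) %% nt + 1
    rj <- (idx - 1) %/% nt + 1
    o <- order(ti, rj)[1]
    ti <- ti[o]
    rj <- rj[o]
    out[[length(out) + 1]] <-
      c(theta = acc$theta[ti], rho = acc$rho[rj], votes = m)
    for (dt in -ht:ht) {
      t <- ti + dt
      if (t >= 1 && t <= nt) {
        cols <- max(1, rj - hr):min(nr, rj + hr)
        v[t, cols] <- 0L
      } else {
        tw <- (t - 1) %% nt + 1
        jf <- nr + 1 - rj  # rho bins are symmetric: flipped sign
        cols <- max(1, jf - hr):min(nr, jf + hr)
        v[tw, cols] <- 0L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(theta = double(), rho = double(),
                          votes = double()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Extract line segments along Hough peaks
#'
#' Bridges infinite Hough lines to per-cell segments: edge pixels within
#' `lateral_tol` of each peak line are projected onto the line, sorted, and
#' chained into maximal runs whose internal gaps do not exceed `max_gap`.
#' Each run whose Euclidean endpoint distance reaches `min_length` becomes a
#' segment carrying its generating `(theta, rho)`. The default floor of 20
#' pixels suppresses noise-level detections and rejects rounded floating
#' cells, whose chords stay short.
#'
#' @param edges Logical `H x W` edge matrix.
#' @param peaks Tibble from [find_peaks()] (columns `theta`, `rho`).
#' @param min_length Minimum Euclidean segment length in pixels (> 0).
#'   Default 20.
#' @param max_gap Largest within-run gap in projected pixels. Default 3.
#' @param lateral_tol Off-line distance tolerance in pixels. Default 2.
#' @return Segment tibble: `x1, y1, x2, y2, theta, rho, length` (zero-based
#'   pixel coordinates; endpoint 1 has the smaller line-parameter).
#' @export
extract_segments <- function(edges, peaks, min_length = 20, max_gap = 3,
                             lateral_tol = 2) {
  stopifnot(is.matrix(edges))
  if (min_length <= 0) stop("min_length must be > 0 (parameter error)")
  pts <- which(edges != 0, arr.ind = TRUE)
  x <- as.numeric(pts[, 2] - 1)
  y <- as.numeric(pts[, 1] - 1)
  rows <- list()
  for (k in seq_len(nrow(peaks))) {
    th <- peaks$theta[k]
    rh <- peaks$rho[k]
    ct <- cos(th)
    st <- sin(th)
    on_line <- abs(x * ct + y * st - rh) <= lateral_tol
    if (!any(on_line)) next
    xs <- x[on_line]
    ys <- y[on_line]
    tpar <- -xs * st + ys * ct  # position along the line direction
    o <- order(tpar, xs, ys)
    xs <- xs[o]
    ys <- ys[o]
    tpar <- tpar[o]
    run_id <- cumsum(c(0, diff(tpar) > max_gap))
    for (rid in unique(run_id)) {
      sel <- run_id == rid
      i1 <- which(sel)[1]
      i2 <- tail(which(sel), 1)
      len <- sqrt((xs[i2] - xs[i1])^2 + (ys[i2] - ys[i1])^2)
      if (len >= min_length) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          x1 = xs[i1], y1 = ys[i1], x2 = xs[i2], y2 = ys[i2],
          theta = th, rho = rh, length = len
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(empty_segment_table())
  }
  dplyr::bind_rows(rows)
}

empty_segment_table <- function() {
  tibble::tibble(
    x1 = double(), y1 = double(), x2 = double(), y2 = double(),
    theta = double(), rho = double(), length = double()
  )
}

#' Build a segment table from endpoints
#'
#' Convenience constructor for the segment tibble used across the package:
#' computes each segment's Euclidean `length` and its normal-form Hough
#' parameters (`theta` in `[0, pi)`, signed `rho`) from the endpoints.
#'
#' @param x1,y1,x2,y2 Endpoint coordinates (vectors, zero-based pixels).
#' @return Segment tibble with `x1, y1, x2, y2, theta, rho, length`.
#' @export
segment_table <- function(x1, y1, x2, y2) {
  theta <- (atan2(y2 - y1, x2 - x1) + pi / 2) %% pi
  rho <- x1 * cos(theta) + y1 * sin(theta)
  tibble::tibble(
    x1 = as.numeric(x1), y1 = as.numeric(y1),
    x2 = as.numeric(x2), y2 = as.numeric(y2),
    theta = theta, rho = rho,
    length = sqrt((x2 - x1)^2 + (y2 - y1)^2)
  )
}
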