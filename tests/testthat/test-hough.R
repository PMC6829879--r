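test_that("single-pixel voting follows the normal form rho = x cos + y sin", {
  edges <- matrix(FALSE, 8, 8)
  edges[1, 2] <- TRUE  # (x, y) = (1, 0)
  acc <- hough_accumulate(edges)
  # at theta = 0 the voted rho bin holds rho = 1
  expect_equal(acc$rho[which(acc$votes[1, ] == 1)], 1)
})

test_that("collinear points share one (theta, rho) bin", {
  edges <- matrix(FALSE, 8, 8)
  edges[1, 1] <- TRUE  # (0, 0)
  edges[2, 2] <- TRUE  # (1, 1)
  acc <- hough_accumulate(edges)
  t135 <- which.min(abs(acc$theta - 3 * pi / 4))
  r0 <- which(acc$rho == 0)
  expect_equal(acc$votes[t135, r0], 2)
})

test_that("an empty edge image yields a valid all-zero accumulator", {
  acc <- hough_accumulate(matrix(FALSE, 16, 16))
  expect_true(all(acc$votes == 0))
  expect_equal(dim(acc$votes), c(length(acc$theta), length(acc$rho)))
})

test_that("accumulator matches the brute-force oracle on random images", {
  set.seed(101)
  for (rep in 1:5) {
    h <- sample(8:32, 1)
    w <- sample(8:32, 1)
    edges <- matrix(runif(h * w) < runif(1, 0.01, 0.1), h, w)
    acc <- hough_accumulate(edges)
    ora <- oracle_hough(edges)
    expect_identical(unname(acc$votes), unname(ora$votes))
    expect_equal(sum(acc$votes), sum(edges) * length(acc$theta))
  }
})

test_that("a single collinear run produces exactly one peak at its line", {
  edges <- matrix(FALSE, 50, 50)
  edges[6, 11:40] <- TRUE  # horizontal run, y = 5, x = 10..39
  acc <- hough_accumulate(edges)
  pk <- find_peaks(acc, min_votes = 20)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$theta - pi / 2), pi / 180 + 1e-9)
  expect_lte(abs(pk$rho - 5), 1)
})

test_that("two orthogonal runs produce exactly two peaks", {
  edges <- matrix(FALSE, 50, 50)
  edges[6, 11:40] <- TRUE   # horizontal
  edges[11:40, 31] <- TRUE  # vertical, x = 30
  pk <- find_peaks(hough_accumulate(edges), min_votes = 20)
  expect_equal(nrow(pk), 2)
  angles <- sort(pk$theta)
  expect_lt(abs(angles[1] - 0), pi / 180 + 1e-9)
  expect_lt(abs(angles[2] - pi / 2), pi / 180 + 1e-9)
})

test_that("an all-zero accumulator yields no peaks", {
  pk <- find_peaks(hough_accumulate(matrix(FALSE, 16, 16)), min_votes = 1)
  expect_equal(nrow(pk), 0)
})

test_that("rotating a line image shifts the detected angle by that amount", {
  cx <- 40
  cy <- 40
  a0 <- 10 * pi / 180
  edges <- rasterize_segment(80, 80, cx - 25 * cos(a0), cy - 25 * sin(a0),
                             cx + 25 * cos(a0), cy + 25 * sin(a0))
  detect_theta <- function(e) {
    find_peaks(hough_accumulate(e), min_votes = 15)$theta[1]
  }
  rotate_image <- function(e, phi) {
    pts <- which(e, arr.ind = TRUE)
    x <- pts[, 2] - 1 - cx
    y <- pts[, 1] - 1 - cy
    xr <- round(x * cos(phi) - y * sin(phi) + cx)
    yr <- round(x * sin(phi) + y * cos(phi) + cy)
    out <- matrix(FALSE, nrow(e), ncol(e))
    out[cbind(yr + 1, xr + 1)] <- TRUE
    out
  }
  phi <- 25 * pi / 180
  shift <- (detect_theta(rotate_image(edges, phi)) - detect_theta(edges)) %% pi
  expect_lte(abs(shift - phi), pi / 180 + 1e-9)
})

test_that("segment extraction recovers a run's endpoints and length", {
  edges <- matrix(FALSE, 50, 50)
  edges[6, 11:40] <- TRUE
  peaks <- tibble::tibble(theta = pi / 2, rho = 5)
  segs <- extract_segments(edges, peaks)
  expect_equal(nrow(segs), 1)
  expect_lte(abs(segs$length - 30), 1.5)
  expect_equal(sort(c(segs$x1, segs$x2)), c(10, 39))
  expect_equal(c(segs$y1, segs$y2), c(5, 5))
})

test_that("runs shorter than the 20-pixel floor are dropped", {
  edges <- matrix(FALSE, 50, 50)
  edges[6, 11:25] <- TRUE  # 15 pixels
  peaks <- tibble::tibble(theta = pi / 2, rho = 5)
  expect_equal(nrow(extract_segments(edges, peaks, min_length = 20)), 0)
})

test_that("runs split by a small gap are chained up to max_gap", {
  edges <- matrix(FALSE, 50, 50)
  edges[6, 1:13] <- TRUE    # x = 0..12
  edges[6, 16:28] <- TRUE   # x = 15..27
  peaks <- tibble::tibble(theta = pi / 2, rho = 5)
  segs <- extract_segments(edges, peaks, max_gap = 3)
  expect_equal(nrow(segs), 1)
  expect_lte(abs(segs$length - 28), 1.5)
  # with a tighter gap the run splits and both halves fall below the floor
  expect_equal(nrow(extract_segments(edges, peaks, max_gap = 2)), 0)
})

test_that("a rounded floating cell yields no segments at the length floor", {
  edges <- matrix(FALSE, 40, 40)
  ang <- seq(0, 2 * pi, length.out = 200)
  xs <- round(20 + 8 * cos(ang))
  ys <- round(20 + 8 * sin(ang))
  edges[cbind(ys + 1, xs + 1)] <- TRUE  # circle, radius 8: max chord 16
  acc <- hough_accumulate(edges)
  pk <- find_peaks(acc, min_votes = 1)
  segs <- extract_segments(edges, pk, min_length = 20)
  expect_equal(nrow(segs), 0)
})

test_that("parameter validation rejects degenerate discretizations", {
  edges <- matrix(FALSE, 8, 8)
  expect_error(hough_accumulate(edges, rho_step = 0), "parameter")
  expect_error(find_peaks(hough_accumulate(edges), min_votes = 0),
               "parameter")
  expect_error(extract_segments(edges, tibble::tibble(theta = 0, rho = 0),
                                min_length = 0), "parameter")
})
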