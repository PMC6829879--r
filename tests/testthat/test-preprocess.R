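test_that("grayscale conversion maps extremes and equal channels exactly", {
  white <- array(255, dim = c(32, 32, 3))
  expect_equal(to_grayscale(white), matrix(1, 32, 32))
  black <- array(0, dim = c(32, 32, 3))
  expect_equal(to_grayscale(black), matrix(0, 32, 32))
  for (v in c(17, 100, 200)) {
    img <- array(v, dim = c(32, 32, 3))
    expect_equal(to_grayscale(img), matrix(v / 255, 32, 32))
  }
  expect_error(to_grayscale(array(0.5, dim = c(32, 32, 4))), "channels")
})

test_that("grayscale accepts already-gray input and minmax rescaling", {
  g <- matrix(runif(64, 0.2, 0.8), 8, 8)
  expect_equal(to_grayscale(g), g)
  mm <- to_grayscale(g, normalize = "minmax")
  expect_equal(range(mm), c(0, 1))
})

test_that("median filter removes salt pixels and matches window oracle", {
  const <- matrix(0.4, 9, 9)
  expect_equal(median_denoise(const, 3), const)

  salt <- matrix(0.2, 9, 9)
  salt[5, 5] <- 1
  expect_equal(median_denoise(salt, 3), matrix(0.2, 9, 9))

  set.seed(11)
  for (k in c(3, 5)) {
    img <- matrix(runif(49), 7, 7)
    expect_equal(median_denoise(img, k), oracle_median(img, k))
  }

  expect_error(median_denoise(const, 4), "parameter")
  expect_error(median_denoise(const, -3), "parameter")
})

test_that("median filter is idempotent on coarse piecewise-constant images", {
  img <- matrix(0.2, 12, 12)
  img[, 7:12] <- 0.8
  once <- median_denoise(img, 3)
  expect_equal(median_denoise(once, 3), once)
})

test_that("cube enhancement applies F = G^3 with fixed points at 0 and 1", {
  expect_equal(enhance_cube(matrix(c(0, 1, 0.5, 0.8), 2, 2)),
               matrix(c(0, 1, 0.125, 0.512), 2, 2))
  expect_error(enhance_cube(matrix(c(0.5, 1.2), 1, 2)), "contract")
})

test_that("cube enhancement is strictly monotone and never brightens", {
  g <- seq(0.01, 0.99, by = 0.01)
  f <- enhance_cube(matrix(g, 1))
  expect_true(all(diff(as.vector(f)) > 0))
  expect_true(all(f <= g))
})

test_that("canny returns an empty binary map on constant input", {
  e <- canny_edges(matrix(0.6, 40, 40))
  expect_type(e, "logical")
  expect_false(any(e))
})

test_that("canny localizes a vertical step at the gradient maximum column", {
  img <- matrix(0.2, 40, 40)
  img[, 21:40] <- 0.8
  e <- canny_edges(img)
  # independent finite-difference oracle for the maximum-gradient columns
  cd <- abs(img[1, -1] - img[1, -40])
  oracle_cols <- which(cd == max(cd))  # between cols 20 and 21
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(length(cols) >= 1)
  expect_true(all(cols %in% c(oracle_cols, oracle_cols + 1)))
  # contiguous vertical edge spanning the frame
  rows <- sort(unique(which(e, arr.ind = TRUE)[, 1]))
  expect_true(all(diff(rows) == 1))
  expect_gte(length(rows), 36)
})

test_that("canny traces a closed loop within 2 px of a rectangle perimeter", {
  img <- matrix(0.9, 60, 60)
  img[20:40, 15:45] <- 0.1
  e <- canny_edges(img)
  pts <- which(e, arr.ind = TRUE)
  # analytic perimeter (1-based matrix coordinates)
  per <- rbind(
    cbind(20, 15:45), cbind(40, 15:45), cbind(20:40, 15), cbind(20:40, 45)
  )
  d_to_per <- function(p) {
    min(sqrt((per[, 1] - p[1])^2 + (per[, 2] - p[2])^2))
  }
  expect_true(all(apply(pts, 1, d_to_per) <= 2))
  # every perimeter point is covered within 2 px (loop is closed)
  d_to_edge <- apply(per, 1, function(p) {
    min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
  })
  expect_true(all(d_to_edge <= 2))
})

test_that("canny edge count is invariant under affine intensity rescaling", {
  img <- matrix(0.75, 50, 50)
  img[15:35, 20:30] <- 0.35
  e1 <- canny_edges(img, low = 0.2, high = 0.5)
  e2 <- canny_edges(0.5 * img + 0.25, low = 0.2, high = 0.5)
  # rounding can flip which side of a flat gradient plateau wins the
  # suppression, but the amount of detected boundary is unchanged
  expect_equal(sum(e1), sum(e2))
  expect_gte(mean(e1 == e2), 0.99)
})

test_that("canny rejects invalid parameters", {
  img <- matrix(0.5, 32, 32)
  expect_error(canny_edges(img, sigma = 0), "parameter")
  expect_error(canny_edges(img, low = 0.6, high = 0.3), "parameter")
})

test_that("the preprocessing chain is deterministic", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  chain <- function() {
    canny_edges(enhance_cube(median_denoise(to_grayscale(img))))
  }
  expect_identical(chain(), chain())
})
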