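test_that("segment distance handles touching, parallel and degenerate cases", {
  a <- c(0, 0, 10, 0)
  expect_equal(segment_min_distance(a, a), 0)
  expect_equal(segment_min_distance(a, c(2, 10, 8, 10)), 10)
  # proper crossing
  expect_equal(segment_min_distance(c(0, -5, 0, 5), c(-5, 0, 5, 0)), 0)
  # degenerate segment treated as a point
  expect_equal(segment_min_distance(c(5, 3, 5, 3), a), 3)
  # symmetry
  b <- c(20, 7, 31, 2)
  expect_equal(segment_min_distance(a, b), segment_min_distance(b, a))
})

test_that("segment distance matches the dense-sampling oracle", {
  set.seed(31)
  for (rep in 1:100) {
    a <- runif(4, 0, 8)
    b <- runif(4, 0, 8)
    expect_lt(abs(segment_min_distance(a, b) - oracle_seg_dist(a, b)), 0.1)
  }
})

test_that("included angle is acute, undirected and wraps at 180 degrees", {
  expect_equal(included_angle(c(0, 0, 10, 0), c(5, 5, 15, 5)), 0)
  expect_equal(included_angle(c(0, 0, 10, 0), c(0, 0, 0, 10)), 90)
  a10 <- c(0, 0, cos(10 * pi / 180), sin(10 * pi / 180))
  a170 <- c(0, 0, cos(170 * pi / 180), sin(170 * pi / 180))
  expect_equal(included_angle(a10, a170), 20, tolerance = 1e-8)
  expect_error(included_angle(c(0, 0, 0, 0), c(0, 0, 1, 1)), "direction")
})

test_that("duplicate removal keeps the longer of two close parallel lines", {
  segs <- segment_table(c(0, 0), c(0, 10), c(30, 25), c(0, 10))
  kept <- remove_duplicates(segs)  # distance 10 < 15, angle 0 < 20
  expect_equal(nrow(kept), 1)
  expect_equal(kept$length, 30)
})

test_that("duplicate removal thresholds are strict on both conditions", {
  # distance 16 fails the 'fewer than 15 pixels' condition: both remain
  segs <- segment_table(c(0, 0), c(0, 16), c(30, 25), c(0, 16))
  expect_equal(nrow(remove_duplicates(segs)), 2)
  # distance 5 but angle 25 degrees: both remain
  segs2 <- segment_table(c(0, 0), c(0, 5),
                         c(30, 25 * cos(25 * pi / 180)),
                         c(0, 5 + 25 * sin(25 * pi / 180)))
  expect_equal(included_angle(segs2[1, ], segs2[2, ]), 25, tolerance = 1e-8)
  expect_equal(nrow(remove_duplicates(segs2)), 2)
  # exactly at both boundaries: both remain (strict inequalities)
  segs3 <- segment_table(c(0, 0), c(0, 15), c(30, 25), c(0, 15))
  expect_equal(nrow(remove_duplicates(segs3)), 2)
})

test_that("duplicate removal is idempotent, shrinking and order-independent", {
  set.seed(41)
  for (rep in 1:10) {
    segs <- random_segments(7)
    kept <- remove_duplicates(segs)
    expect_lte(nrow(kept), nrow(segs))
    expect_equal(remove_duplicates(kept), kept)
    perm <- segs[sample(nrow(segs)), ]
    kept_perm <- remove_duplicates(perm)
    expect_equal(dplyr::arrange(kept_perm, x1, y1, x2, y2),
                 dplyr::arrange(kept, x1, y1, x2, y2))
  }
})

test_that("duplicate removal agrees with the exhaustive subset oracle", {
  set.seed(43)
  for (rep in 1:15) {
    segs <- random_segments(sample(2:8, 1), box = 30)
    expect_equal(remove_duplicates(segs), oracle_remove_duplicates(segs))
  }
})

test_that("segments sharing an endpoint merge into one piecewise line", {
  segs <- segment_table(c(0, 20), c(0, 0), c(20, 35), c(0, 10))
  cells <- merge_fragments(segs)
  expect_equal(unique(cells$cell_id), 1L)
  pl <- polyline_length(cells)
  expect_equal(pl$total_length, 20 + sqrt(15^2 + 10^2))
  expect_equal(pl$n_segments, 2L)
})

test_that("distant segments stay separate; touching chains merge transitively", {
  far <- segment_table(c(0, 100), c(0, 100), c(20, 120), c(0, 100))
  expect_equal(dplyr::n_distinct(merge_fragments(far)$cell_id), 2)
  chain <- segment_table(c(0, 20, 40), c(0, 0, 20), c(20, 40, 60),
                         c(0, 20, 20))
  cells <- merge_fragments(chain)
  expect_equal(unique(cells$cell_id), 1L)
  expect_equal(polyline_length(cells)$n_segments, 3L)
})

test_that("merging conserves total length and never increases cell count", {
  set.seed(47)
  for (rep in 1:10) {
    segs <- remove_duplicates(random_segments(8))
    cells <- merge_fragments(segs)
    expect_equal(sum(polyline_length(cells)$total_length),
                 sum(segs$length))
    expect_lte(dplyr::n_distinct(cells$cell_id), nrow(segs))
  }
})

test_that("polyline length sums Euclidean member lengths", {
  single <- merge_fragments(segment_table(0, 0, 30, 0))
  expect_equal(polyline_length(single)$total_length, 30)
  pythag <- merge_fragments(segment_table(0, 0, 3, 4))
  expect_equal(polyline_length(pythag)$total_length, 5)
  ell <- merge_fragments(segment_table(c(0, 20), c(0, 0), c(20, 20),
                                       c(0, 20)))
  expect_equal(polyline_length(ell)$total_length, 40)
  expect_error(polyline_length(merge_fragments(segment_table(
    numeric(0), numeric(0), numeric(0), numeric(0)))), "contract")
})
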