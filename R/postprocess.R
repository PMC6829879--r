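#' Remove duplicate near-parallel detections
#'
#' One cell boundary can be marked by several nearly parallel lines; when
#' the minimal distance between two segments is below `dist_thresh` (strict)
#' and their included angle is below `angle_thresh` (strict), the shorter
#' segment is removed and the longer one kept. Conflicts among more than two
#' segments are resolved greedily: segments are considered in decreasing
#' length (ties by `theta`, `rho`, `x1`, `y1`), and a segment is accepted
#' exactly when it conflicts with no already-accepted segment. The result is
#' conflict-free, deterministic, and idempotent.
#'
#' @param segs Segment tibble (`x1, y1, x2, y2, theta, rho, length`).
#' @param dist_thresh Distance threshold in pixels (> 0). Default 15.
#' @param angle_thresh Angle threshold in degrees (> 0). Default 20.
#' @return Filtered segment tibble (subset of the input rows).
#' @export
remove_duplicates <- function(segs, dist_thresh = 15, angle_thresh = 20) {
  if (dist_thresh <= 0 || angle_thresh <= 0) {
    stop("thresholds must be > 0 (parameter error)")
  }
  n <- nrow(segs)
  if (n <= 1) return(segs)
  ord <- order(-segs$length, segs$theta, segs$rho, segs$x1, segs$y1)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0) {
      accepted <- i
      next
    }
    d <- seg_pair_min_dist(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i],
                           segs$x1[accepted], segs$y1[accepted],
                           segs$x2[accepted], segs$y2[accepted])
    a <- seg_pair_angle(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i],
                        segs$x1[accepted], segs$y1[accepted],
                        segs$x2[accepted], segs$y2[accepted])
    if (!any(d < dist_thresh & a < angle_thresh)) {
      accepted <- c(accepted, i)
    }
  }
  segs[sort(accepted), , drop = FALSE]
}

#' Merge fragmented detections into piecewise lines
#'
#' A slender cell is often described by several discrete segments; segments
#' that intersect or whose endpoints lie within `join_tol` of the other
#' segment's endpoints are integrated into one piecewise line (a polyline
#' cell). Merging takes the transitive closure of that relation, so the
#' output assigns every segment a `cell_id`; isolated segments become
#' single-segment cells. Total summed length is conserved.
#'
#' @param segs Deduplicated segment tibble.
#' @param join_tol Endpoint gap tolerance in pixels. Default 5 (kept below
#'   the 15-pixel duplicate radius so distinct neighboring cells are not
#'   re-merged).
#' @return The segment tibble with a `cell_id` column (integers, numbered
#'   in order of first appearance).
#' @export
merge_fragments <- function(segs, join_tol = 5) {
  n <- nrow(segs)
  if (n == 0) {
    return(dplyr::mutate(segs, cell_id = integer(0)))
  }
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]
  j <- pairs[, 2]
  touch <- logical(length(i))
  if (length(i) > 0) {
    dist <- seg_pair_min_dist(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i],
                              segs$x1[j], segs$y1[j], segs$x2[j], segs$y2[j])
    ep_gap <- pmin(
      sqrt((segs$x1[i] - segs$x1[j])^2 + (segs$y1[i] - segs$y1[j])^2),
      sqrt((segs$x1[i] - segs$x2[j])^2 + (segs$y1[i] - segs$y2[j])^2),
      sqrt((segs$x2[i] - segs$x1[j])^2 + (segs$y2[i] - segs$y1[j])^2),
      sqrt((segs$x2[i] - segs$x2[j])^2 + (segs$y2[i] - segs$y2[j])^2)
    )
    touch <- dist <= 1e-9 | ep_gap <= join_tol
  }
  g <- igraph::graph_from_edgelist(
    cbind(c(i[touch], seq_len(n)), c(j[touch], seq_len(n))),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership[seq_len(n)]
  # renumber components in order of first appearance
  cell_id <- match(comp, unique(comp))
  dplyr::mutate(segs, cell_id = cell_id)
}

#' Per-cell polyline lengths
#'
#' Sums member segment lengths per polyline cell: the reported length of a
#' slender cell is the total length of its merged piecewise line.
#'
#' @param cells Output of [merge_fragments()] (segments with `cell_id`).
#' @return Tibble with `cell_id`, `n_segments`, `total_length` (pixels).
#' @export
polyline_length <- function(cells) {
  if (!"cell_id" %in% names(cells)) {
    stop("input must carry a cell_id column (run merge_fragments first)")
  }
  if (nrow(cells) == 0) {
    stop("empty polyline has no length (contract violation)")
  }
  dplyr::summarise(
    dplyr::group_by(cells, .data$cell_id),
    n_segments = dplyr::n(),
    total_length = sum(.data$length),
    .groups = "drop"
  )
}
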