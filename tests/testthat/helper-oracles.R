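# Independent brute-force oracles used across the suite. These re-derive
# expected values by the dumbest correct method available and are kept free
# of any package internals beyond exported constructors.

# per-pixel window median with replicated borders
oracle_median <- function(img, kernel) {
  r <- kernel %/% 2
  h <- nrow(img)
  w <- ncol(img)
  out <- img
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- pmin(pmax((i - r):(i + r), 1), h)
      jj <- pmin(pmax((j - r):(j + r), 1), w)
      v <- sort(as.vector(img[ii, jj]))
      out[i, j] <- v[(length(v) + 1) / 2]
    }
  }
  out
}

# double loop over edge pixels and theta bins; same nearest-bin convention
# (ties rounded away from zero, as for any non-negative offset)
oracle_hough <- function(edges, theta_step = pi / 180, rho_step = 1) {
  n_theta <- floor(pi / theta_step + 1e-9)
  theta <- (seq_len(n_theta) - 1) * theta_step
  d <- ceiling(sqrt((nrow(edges) - 1)^2 + (ncol(edges) - 1)^2))
  rho <- seq(-d, d, by = rho_step)
  votes <- matrix(0L, n_theta, length(rho))
  pts <- which(edges, arr.ind = TRUE)
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, 2] - 1
    y <- pts[p, 1] - 1
    for (t in seq_len(n_theta)) {
      r <- x * cos(theta[t]) + y * sin(theta[t])
      j <- floor((r + d) / rho_step + 0.5) + 1
      j <- min(max(j, 1), length(rho))
      votes[t, j] <- votes[t, j] + 1L
    }
  }
  list(votes = votes, theta = theta, rho = rho)
}

# dense-sampling segment-segment distance
oracle_seg_dist <- function(a, b, n = 150) {
  t <- seq(0, 1, length.out = n)
  ax <- a[1] + t * (a[3] - a[1])
  ay <- a[2] + t * (a[4] - a[2])
  bx <- b[1] + t * (b[3] - b[1])
  by <- b[2] + t * (b[4] - b[2])
  min(sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2))
}

# exhaustive duplicate-removal oracle: enumerate all conflict-free subsets
# and keep the one that is lexicographically maximal under the
# length-favoring order (length desc, then theta, rho, x1, y1)
oracle_remove_duplicates <- function(segs, dist_thresh = 15,
                                     angle_thresh = 20) {
  n <- nrow(segs)
  if (n == 0) return(segs)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- segment_min_distance(segs[i, ], segs[j, ])
      a <- included_angle(segs[i, ], segs[j, ])
      conflict[i, j] <- conflict[j, i] <-
        (d < dist_thresh) && (a < angle_thresh)
    }
  }
  ord <- order(-segs$length, segs$theta, segs$rho, segs$x1, segs$y1)
  rank_of <- match(seq_len(n), ord)
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) > 1 &&
        any(conflict[members, members])) next
    key <- sort(rank_of[members])
    # lexicographic: prefer the subset containing the highest-priority
    # (lowest-rank) segments first; pad with Inf
    cmp <- function(k1, k2) {
      l <- max(length(k1), length(k2))
      k1 <- c(k1, rep(Inf, l - length(k1)))
      k2 <- c(k2, rep(Inf, l - length(k2)))
      dif <- k1 - k2
      nz <- which(dif != 0)
      if (length(nz) == 0) 0 else if (dif[nz[1]] < 0) 1 else -1
    }
    if (is.null(best) || cmp(key, best_key) > 0) {
      best <- members
      best_key <- key
    }
  }
  segs[sort(best), , drop = FALSE]
}

# brute-force optimal one-to-one assignment cost (midpoint distances)
oracle_assignment_cost <- function(cost_matrix) {
  nd <- nrow(cost_matrix)
  nt <- ncol(cost_matrix)
  k <- min(nd, nt)
  best <- Inf
  if (nd <= nt) {
    perms <- gtools_permutations(nt, nd)
    for (r in seq_len(nrow(perms))) {
      cst <- sum(cost_matrix[cbind(seq_len(nd), perms[r, ])])
      best <- min(best, cst)
    }
  } else {
    perms <- gtools_permutations(nd, nt)
    for (r in seq_len(nrow(perms))) {
      cst <- sum(cost_matrix[cbind(perms[r, ], seq_len(nt))])
      best <- min(best, cst)
    }
  }
  best
}

# all k-permutations of 1..n (small n only)
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- gtools_permutations(n - 1, k - 1)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}

# rasterize an analytic segment into an edge matrix (dense pixel chain)
rasterize_segment <- function(h, w, x1, y1, x2, y2) {
  edges <- matrix(FALSE, h, w)
  n <- max(2, ceiling(2 * sqrt((x2 - x1)^2 + (y2 - y1)^2)))
  t <- seq(0, 1, length.out = n)
  xs <- round(x1 + t * (x2 - x1))
  ys <- round(y1 + t * (y2 - y1))
  ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
  edges[cbind(ys[ok] + 1, xs[ok] + 1)] <- TRUE
  edges
}

# random segment table in a bounding box (clustered to provoke conflicts)
random_segments <- function(n, box = 40, min_len = 5, max_len = 25) {
  x1 <- runif(n, 0, box)
  y1 <- runif(n, 0, box)
  ang <- runif(n, 0, pi)
  len <- runif(n, min_len, max_len)
  segment_table(x1, y1, x1 + len * cos(ang), y1 + len * sin(ang))
}
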