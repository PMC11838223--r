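# Shared generators and brute-force oracles for the test suite.

# sparse-leukemia type mixture used when planted spatial structure must be
# detectable (dense leukemia makes almost every cell "near")
sparse_props <- function() {
  c(leukemia = 0.1, erythroid = 0.4, CD14_monocyte = 0.2,
    monocyte_progenitor = 0.1, T_CD4_naive = 0.1, T_CD8 = 0.05,
    DC = 0.03, B = 0.02)
}

# random star-shaped simple polygon around a center
random_polygon <- function(n = 8, center = c(0, 0), r = 1) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.5 * r, r)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# n points spread uniformly along a polygon's boundary
sample_boundary <- function(P, n) {
  P2 <- rbind(P, P[1, ])
  seglen <- sqrt(diff(P2[, 1])^2 + diff(P2[, 2])^2)
  cum <- c(0, cumsum(seglen))
  s <- seq(0, sum(seglen), length.out = n + 1)[-(n + 1)]
  i <- pmin(findInterval(s, cum, rightmost.closed = FALSE), nrow(P))
  t <- (s - cum[i]) / seglen[i]
  cbind(P2[i, 1] + t * (P2[i + 1, 1] - P2[i, 1]),
        P2[i, 2] + t * (P2[i + 1, 2] - P2[i, 2]))
}

# exact distance from many points to one segment, vectorized over points
pt_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

# brute-force polygon min distance: boundary samples of each polygon
# against the exact segments of the other
brute_poly_dist <- function(A, B, n_pts = 5000) {
  segs <- function(P) cbind(P, rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE]))
  best <- Inf
  pa <- sample_boundary(A, n_pts)
  for (k in seq_len(nrow(B))) {
    s <- segs(B)[k, ]
    best <- min(best, pt_seg_dist(pa[, 1], pa[, 2], s[1], s[2], s[3], s[4]))
  }
  pb <- sample_boundary(B, n_pts)
  for (k in seq_len(nrow(A))) {
    s <- segs(A)[k, ]
    best <- min(best, pt_seg_dist(pb[, 1], pb[, 2], s[1], s[2], s[3], s[4]))
  }
  best
}

# even-odd point-in-polygon (reference implementation)
pip_oracle <- function(px, py, P) {
  n <- nrow(P); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if ((P[i, 2] > py) != (P[j, 2] > py) &&
        px < (P[j, 1] - P[i, 1]) * (py - P[i, 2]) / (P[j, 2] - P[i, 2]) + P[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# unit square polygon at an offset
square_at <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}
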