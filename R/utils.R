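#' @keywords internal
"_PACKAGE"

## Internal geometry / RNG helpers shared by the synthetic generator and
## the segmentation layer.  Raster convention throughout the package:
## numeric matrices indexed [row, col], row 1 at the top, 0-based maths
## avoided -- R's 1-based indices are used everywhere.  Centroids are
## (row, col) pairs in pixel units.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards (generators must not disturb user RNG).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Pixel offsets (row, col) of a filled disc of radius r centred at origin.
disc_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = s, dc = s)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# Stamp value `v` over discs of radius r centred at (rows, cols) into matrix m
# (max-composited, clipped to the raster).
stamp_discs <- function(m, rows, cols, r, v) {
  if (length(rows) == 0L) return(m)
  off <- disc_offsets(r)
  H <- nrow(m); W <- ncol(m)
  for (i in seq_along(rows)) {
    rr <- rows[i] + off[, 1L]; cc <- cols[i] + off[, 2L]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx <- cbind(rr[ok], cc[ok])
    m[idx] <- pmax(m[idx], v)
  }
  m
}

# Logical mask of discs of radius r at the given centres.
disc_mask <- function(H, W, rows, cols, r) {
  m <- matrix(0, H, W)
  m <- stamp_discs(m, rows, cols, r, 1)
  m > 0
}

# Elliptical ring mask: outer semi-axes (a, b), ring thickness t (pixels).
ring_mask <- function(H, W, cy, cx, a, b, t) {
  ra <- ceiling(a); rb <- ceiling(b)
  rows <- pmax(1L, cy - ra):pmin(H, cy + ra)
  cols <- pmax(1L, cx - rb):pmin(W, cx + rb)
  dr <- outer(rows - cy, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cx)
  outer_e <- (dr / a)^2 + (dc / b)^2 <= 1
  inner_e <- (dr / (a - t))^2 + (dc / (b - t))^2 <= 1
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- outer_e & !inner_e
  m
}

ellipse_mask <- function(H, W, cy, cx, a, b) {
  ra <- ceiling(a); rb <- ceiling(b)
  rows <- pmax(1L, cy - ra):pmin(H, cy + ra)
  cols <- pmax(1L, cx - rb):pmin(W, cx + rb)
  dr <- outer(rows - cy, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cx)
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- (dr / a)^2 + (dc / b)^2 <= 1
  m
}

# Concentric hexagonal layout for k points with pairwise spacing >= s,
# rotated by `rot` radians; returns k x 2 matrix of (drow, dcol) offsets.
cluster_layout <- function(k, s, rot = 0) {
  stopifnot(k >= 1, k <= 19)
  if (k == 1L) return(matrix(0, 1, 2))
  if (k == 2L) pts <- rbind(c(-s / 2, 0), c(s / 2, 0))
  else if (k == 3L) {
    r <- s / sqrt(3)
    ang <- 2 * pi * (0:2) / 3
    pts <- cbind(r * sin(ang), r * cos(ang))
  } else if (k == 4L) {
    r <- s / sqrt(2)
    ang <- 2 * pi * (0:3) / 4 + pi / 4
    pts <- cbind(r * sin(ang), r * cos(ang))
  } else {
    # centre + ring of 6 at radius s + ring of 12 at radius 2s
    pts <- matrix(0, 1, 2)
    n1 <- min(k - 1L, 6L)
    ang <- 2 * pi * seq_len(n1) / 6
    pts <- rbind(pts, cbind(s * sin(ang), s * cos(ang)))
    n2 <- k - 1L - n1
    if (n2 > 0L) {
      ang <- 2 * pi * seq_len(n2) / 12
      pts <- rbind(pts, cbind(2 * s * sin(ang), 2 * s * cos(ang)))
    }
  }
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
  pts %*% R
}

# Radius of the smallest origin-centred circle containing the layout.
layout_radius <- function(pts) if (nrow(pts) == 1L) 0 else max(sqrt(rowSums(pts^2)))

`%||%` <- function(a, b) if (is.null(a)) b else a
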