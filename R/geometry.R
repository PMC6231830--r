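# Internal planar-geometry helpers. Coordinates are planar metres throughout;
# polygons are two-column matrices (x, y), not necessarily closed.

# Shoelace area of a simple polygon (m^2).
polygon_area <- function(xy) {
  if (is.null(dim(xy)) || nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull as a counter-clockwise, unclosed coordinate matrix.
convex_hull <- function(xy) {
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3) return(xy)
  xy[rev(chull(xy)), , drop = FALSE]
}

# Logical vector: is each point of `pts` inside polygon `poly`?
points_in_polygon <- function(pts, poly) {
  if (nrow(pts) == 0) return(logical(0))
  if (is.null(dim(poly)) || nrow(poly) < 3) return(rep(FALSE, nrow(pts)))
  mgcv::in.out(rbind(as.matrix(poly), poly[1, , drop = FALSE]), as.matrix(pts))
}

# Mean-preserving blockwise nearest-neighbour distances within one point set.
# O(n^2) arithmetic but bounded memory; fine for village-scale n.
nn_distances <- function(xy, block = 512L) {
  n <- nrow(xy)
  if (n < 2) stop("at least two points are required", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

# Uniform-grid spatial index over a point set, for nearest-point queries.
# Hand-rolled because no spatial-index package ships with the environment;
# exactness versus a brute-force scan is asserted in the test suite.
point_grid_index <- function(xy, cellsize = NULL) {
  stopifnot(nrow(xy) >= 1)
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  if (is.null(cellsize)) {
    span <- max(xr[2] - xr[1], yr[2] - yr[1], 1)
    cellsize <- max(span / max(1, ceiling(sqrt(nrow(xy)))), 1e-9)
  }
  ix <- floor((xy[, 1] - xr[1]) / cellsize)
  iy <- floor((xy[, 2] - yr[1]) / cellsize)
  key <- paste(ix, iy)
  structure(list(xy = xy, x0 = xr[1], y0 = yr[1], cellsize = cellsize,
                 cells = split(seq_len(nrow(xy)), key),
                 ix_rng = range(ix), iy_rng = range(iy)),
            class = "point_grid_index")
}

# Nearest indexed point for each query point; returns list(index, distance).
# Expanding-ring search with a guaranteed-correct stopping rule: a ring at
# Chebyshev radius r can only contain points nearer than (r-1)*cellsize, so
# once best < (r-1)*cellsize the search is complete.
query_nearest_point <- function(index, qx, qy) {
  m <- length(qx)
  best_i <- integer(m); best_d <- numeric(m)
  cs <- index$cellsize
  for (q in seq_len(m)) {
    cx <- floor((qx[q] - index$x0) / cs)
    cy <- floor((qy[q] - index$y0) / cs)
    bi <- NA_integer_; bd <- Inf
    r <- 0L
    max_r <- max(abs(cx - index$ix_rng), abs(cy - index$iy_rng)) + 1L
    repeat {
      ring <- if (r == 0L) cbind(cx, cy) else {
        s <- (-r):r
        unique(rbind(cbind(cx + s, cy - r), cbind(cx + s, cy + r),
                     cbind(cx - r, cy + s), cbind(cx + r, cy + s)))
      }
      keys <- paste(ring[, 1], ring[, 2])
      ids <- unlist(index$cells[keys], use.names = FALSE)
      if (length(ids)) {
        d <- sqrt((index$xy[ids, 1] - qx[q])^2 + (index$xy[ids, 2] - qy[q])^2)
        k <- which.min(d)
        if (d[k] < bd) { bd <- d[k]; bi <- ids[k] }
      }
      if ((is.finite(bd) && bd <= (r - 1) * cs) || r > max_r) break
      r <- r + 1L
    }
    best_i[q] <- bi; best_d[q] <- bd
  }
  list(index = best_i, distance = best_d)
}
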