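# Planar geometry primitives shared by all modules.
# All coordinates are projected metric (x east, y north); no CRS handling here.

#' Total length of a polyline
#'
#' @param xy two-column matrix of vertices (x, y) in meters.
#' @return Length in meters (0 for a single vertex).
#' @export
path_length <- function(xy) {
  xy <- as_xy(xy)
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# coerce to a 2-column numeric matrix, failing loudly
as_xy <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (!is.matrix(xy) || ncol(xy) < 2)
    stop("expected a two-column matrix of coordinates")
  storage.mode(xy) <- "double"
  xy[, 1:2, drop = FALSE]
}

#' Resample a polyline at fixed arc-length spacing
#'
#' Vertices are placed every `step_m` meters along the piecewise-linear path;
#' both endpoints are preserved (the last inter-vertex gap may be shorter than
#' `step_m` when the total length is not a multiple of the step).
#'
#' @param xy two-column matrix of vertices.
#' @param step_m spacing in meters (default 1).
#' @param keep_vertices also keep the input vertices (default TRUE): corners
#'   are not cut, so the total length is preserved exactly and inter-vertex
#'   spacing stays at most `step_m`. Set FALSE for strictly equal spacing
#'   (e.g. placing GPS fixes every `step_m` along a finely sampled path).
#' @return Two-column matrix of resampled vertices with attribute `"s"`, the
#'   arc-length position of each vertex.
#' @export
resample_path <- function(xy, step_m = 1, keep_vertices = TRUE) {
  xy <- as_xy(xy)
  if (nrow(xy) < 2) stop("cannot resample a path with fewer than 2 points")
  if (step_m <= 0) stop("step_m must be positive")
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  keep <- c(TRUE, seg > 0)            # drop exactly repeated vertices
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 2) stop("path has zero length")
  s <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
  L <- s[length(s)]
  t <- seq(0, L, by = step_m)
  if (t[length(t)] < L - 1e-9) t <- c(t, L)
  if (keep_vertices) {
    t <- sort(unique(c(t, s)))
    t <- t[c(TRUE, diff(t) > 1e-9)]
  }
  out <- cbind(
    x = stats::approx(s, xy[, 1], xout = t)$y,
    y = stats::approx(s, xy[, 2], xout = t)$y
  )
  attr(out, "s") <- t
  attr(out, "step_m") <- step_m
  out
}

#' Distances from points to a polyline
#'
#' Exact minimum Euclidean distance from each query point to the union of the
#' polyline's segments.
#'
#' @param pts two-column matrix of query points.
#' @param path two-column matrix of polyline vertices.
#' @return Numeric vector of distances (meters).
#' @export
dist_to_path <- function(pts, path) {
  pts <- as_xy(pts); path <- as_xy(path)
  n <- nrow(pts)
  if (nrow(path) == 1) {
    return(sqrt((pts[, 1] - path[1, 1])^2 + (pts[, 2] - path[1, 2])^2))
  }
  best <- rep(Inf, n)
  px <- pts[, 1]; py <- pts[, 2]
  for (k in seq_len(nrow(path) - 1)) {
    d <- .dist_to_segment(px, py, path[k, 1], path[k, 2],
                          path[k + 1, 1], path[k + 1, 2])
    best <- pmin(best, d)
  }
  best
}

# vectorised point-to-segment distance
.dist_to_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Works for simple polygons and for multi-ring inputs (a list of rings);
#' with nested rings the even-odd parity makes inner rings holes.
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column matrix (one ring, closed or open) or list of rings.
#' @return Logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- as_xy(pts)
  rings <- if (is.list(poly) && !is.data.frame(poly)) poly else list(poly)
  crossings <- integer(nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (ring in rings) {
    r <- as_xy(ring)
    # drop an explicit closing vertex
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    nv <- nrow(r)
    if (nv < 3) next
    j <- nv
    for (i in seq_len(nv)) {
      xi <- r[i, 1]; yi <- r[i, 2]; xj <- r[j, 1]; yj <- r[j, 2]
      hit <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      crossings <- crossings + as.integer(hit)
      j <- i
    }
  }
  crossings %% 2L == 1L
}

#' Polygon area by the shoelace formula
#'
#' @param poly ring matrix or list of rings; nested rings are treated as holes
#'   (their signed areas cancel when wound oppositely; for same-wound nested
#'   rings use `point_in_polygon`-based grid areas instead).
#' @return Absolute area in square meters (summed over rings).
#' @export
polygon_area <- function(poly) {
  rings <- if (is.list(poly) && !is.data.frame(poly)) poly else list(poly)
  tot <- 0
  for (ring in rings) {
    r <- as_xy(ring)
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) next
    x <- r[, 1]; y <- r[, 2]
    i2 <- c(2:nrow(r), 1)
    tot <- tot + abs(sum(x * y[i2] - x[i2] * y)) / 2
  }
  tot
}

#' Local travel bearings along a resampled path
#'
#' The bearing at each vertex is taken over a centered window of `window_m`
#' arc length (clipped at the ends), which smooths out fix-level jitter.
#' Bearings are reported in degrees in [0, 180) -- i.e. modulo 180, so a path
#' travelled in either direction yields the same bearing.
#'
#' @param xy resampled polyline (output of [resample_path()]).
#' @param window_m smoothing window in meters (default 10).
#' @return Numeric vector of bearings, one per vertex.
#' @export
path_bearings <- function(xy, window_m = 10) {
  s <- attr(xy, "s")
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (is.null(s)) s <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
  half <- window_m / 2
  # window endpoints: i1 = last vertex at or before s - w/2 (min 1),
  # i2 = first vertex at or after s + w/2 (max n)
  i1 <- pmax(1L, findInterval(s - half, s))
  i2 <- pmin(n, findInterval(s + half - 1e-9, s) + 1L)
  bad <- i2 <= i1
  if (any(bad)) {
    i <- seq_len(n)
    i1[bad] <- pmax(1L, i[bad] - 1L)
    i2[bad] <- pmin(n, i[bad] + 1L)
  }
  ang <- atan2(xy[i2, 2] - xy[i1, 2], xy[i2, 1] - xy[i1, 1]) * 180 / pi
  ang %% 180
}

# acute difference between two mod-180 bearings
bearing_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Does a segment intersect an axis-aligned rectangle?
#'
#' Closed-boundary convention: touching the boundary (including a corner)
#' counts as intersecting.
#'
#' @param ax,ay,bx,by segment endpoints.
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Logical scalar.
#' @export
segment_intersects_rect <- function(ax, ay, bx, by, xmin, xmax, ymin, ymax) {
  # quick accept: an endpoint inside
  inside <- function(x, y) x >= xmin && x <= xmax && y >= ymin && y <= ymax
  if (inside(ax, ay) || inside(bx, by)) return(TRUE)
  # quick reject: bounding boxes disjoint
  if (max(ax, bx) < xmin || min(ax, bx) > xmax ||
      max(ay, by) < ymin || min(ay, by) > ymax) return(FALSE)
  # Liang-Barsky clipping
  dx <- bx - ax; dy <- by - ay
  p <- c(-dx, dx, -dy, dy)
  q <- c(ax - xmin, xmax - ax, ay - ymin, ymax - ay)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(FALSE)
    } else {
      t <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Sample points uniformly inside a polygon, excluding gap polygons
#'
#' Rejection sampling from the polygon's bounding box.
#'
#' @param n number of points.
#' @param poly target polygon (ring matrix or list of rings).
#' @param holes optional list of polygons to exclude.
#' @param max_tries rejection budget multiplier.
#' @return n x 2 matrix of points.
#' @export
runif_in_polygon <- function(n, poly, holes = NULL, max_tries = 200) {
  rings <- if (is.list(poly) && !is.data.frame(poly)) poly else list(poly)
  allv <- do.call(rbind, lapply(rings, as_xy))
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  out <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2L * (n - nrow(out)), 64L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    ok <- point_in_polygon(cand, rings)
    if (!is.null(holes) && length(holes)) {
      for (h in holes) ok <- ok & !point_in_polygon(cand, h)
    }
    out <- rbind(out, cand[ok, , drop = FALSE])
    tries <- tries + 1
  }
  if (nrow(out) < n)
    stop("sampling region appears (nearly) empty: polygon minus holes")
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Scale a polygon about its centroid
#'
#' @param poly ring matrix.
#' @param factor scale factor.
#' @return Scaled ring matrix.
#' @export
scale_polygon <- function(poly, factor) {
  r <- as_xy(poly)
  ctr <- colMeans(r)
  cbind(x = ctr[1] + (r[, 1] - ctr[1]) * factor,
        y = ctr[2] + (r[, 2] - ctr[2]) * factor)
}

# evaluate code with a temporary RNG state seeded from `seed`
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# deterministic sub-seed for a named module stream
module_seed <- function(master, stream) {
  offs <- c(dem = 101L, gaps = 202L, trees = 303L, routes = 404L,
            bouts = 505L, scans = 606L, presence = 707L, csr = 808L,
            models = 909L)
  if (!stream %in% names(offs)) stop("unknown RNG stream: ", stream)
  (as.integer(master) + offs[[stream]]) %% 2000000000L
}
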