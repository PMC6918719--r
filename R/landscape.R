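# Quadrat grid and per-quadrat landscape covariates: elevation (bilinear at
# the cell center), slope (8-neighbour maximum rate of change), canopy-gap
# coverage within a 25 m buffer, route presence/absence, and flags for
# intergroup overlap and core-area membership.

#' Lay a quadrat grid over a home range
#'
#' Axis-aligned square cells with the grid origin at the floor of the polygon
#' bounds; a cell belongs to the grid when its center falls inside the
#' polygon.
#'
#' @param home_range polygon (ring matrix or list of rings).
#' @param cell_m cell edge length (default 10 m).
#' @return data.frame `cell_id`, `cx`, `cy`, `row`, `col` (grid indices).
#' @export
make_grid <- function(home_range, cell_m = 10) {
  rings <- if (is.list(home_range) && !is.data.frame(home_range)) home_range
           else list(home_range)
  allv <- do.call(rbind, lapply(rings, as_xy))
  if (nrow(allv) < 3 || polygon_area(rings) == 0)
    stop("degenerate home-range polygon")
  x0 <- floor(min(allv[, 1]) / cell_m) * cell_m
  y0 <- floor(min(allv[, 2]) / cell_m) * cell_m
  xs <- seq(x0 + cell_m / 2, max(allv[, 1]), by = cell_m)
  ys <- seq(y0 + cell_m / 2, max(allv[, 2]), by = cell_m)
  centers <- cbind(x = rep(xs, times = length(ys)),
                   y = rep(ys, each = length(xs)))
  inside <- point_in_polygon(centers, rings)
  out <- data.frame(cell_id = seq_len(sum(inside)),
                    cx = centers[inside, 1], cy = centers[inside, 2])
  out$col <- round((out$cx - x0 - cell_m / 2) / cell_m) + 1L
  out$row <- round((out$cy - y0 - cell_m / 2) / cell_m) + 1L
  attr(out, "cell_m") <- cell_m
  attr(out, "origin") <- c(x0, y0)
  out
}

#' Slope at quadrat centers (8-neighbour maximum rate of change)
#'
#' For each quadrat, elevation is sampled at its center and at the centers of
#' its up-to-8 adjacent quadrats; the slope is the arctangent of the maximum
#' absolute elevation change per horizontal distance (`cell_m` orthogonally,
#' `cell_m * sqrt(2)` diagonally). Edge cells use their available neighbours;
#' a cell with no neighbours at all is an error.
#'
#' @param dem a `route_dem`.
#' @param grid quadrat grid from [make_grid()] (or any data.frame with
#'   `cx`, `cy`, `row`, `col`).
#' @param cell_m cell size (defaults to the grid's).
#' @return Numeric vector of slopes in degrees, parallel to `grid` rows.
#' @export
slope_at <- function(dem, grid, cell_m = attr(grid, "cell_m")) {
  if (is.null(cell_m)) cell_m <- 10
  z0 <- dem_extract(dem, cbind(grid$cx, grid$cy))
  key <- paste(grid$row, grid$col)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  best <- rep(-Inf, nrow(grid))
  nnb <- integer(nrow(grid))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    dist <- cell_m * sqrt(dr^2 + dc^2)
    j <- match(paste(grid$row + dr, grid$col + dc), key)
    ok <- !is.na(j)
    nnb[ok] <- nnb[ok] + 1L
    grad <- abs(z0[ok] - z0[j[ok]]) / dist
    best[ok] <- pmax(best[ok], grad)
  }
  if (any(nnb == 0))
    stop("quadrat(s) with no adjacent quadrat: ",
         paste(which(nnb == 0), collapse = ", "))
  atan(best) * 180 / pi
}

#' Canopy-gap coverage around a quadrat center
#'
#' Percentage of a disc of radius `radius_m` around the cell center that is
#' overlapped by gap polygons, computed by regular quadrature (points on a
#' `quad_step` grid inside the disc).
#'
#' @param cell_center `c(x, y)` or a matrix of centers.
#' @param gap_polygons list of gap polygons (possibly empty).
#' @param radius_m buffer radius (default 25 m).
#' @param quad_step quadrature spacing (default 0.5 m; ~7850 points).
#' @return Percentage(s) in `[0, 100]`.
#' @export
gap_coverage <- function(cell_center, gap_polygons, radius_m = 25,
                         quad_step = 0.5) {
  if (radius_m <= 0) stop("radius_m must be positive")
  ctrs <- if (is.matrix(cell_center) || is.data.frame(cell_center))
    as_xy(cell_center) else matrix(cell_center, 1, 2)
  if (!length(gap_polygons)) return(rep(0, nrow(ctrs)))
  g <- seq(-radius_m + quad_step / 2, radius_m, by = quad_step)
  disc <- expand.grid(dx = g, dy = g)
  disc <- disc[disc$dx^2 + disc$dy^2 <= radius_m^2, ]
  if (nrow(ctrs) == 1) {
    pts <- cbind(ctrs[1, 1] + disc$dx, ctrs[1, 2] + disc$dy)
    inside <- rep(FALSE, nrow(pts))
    for (gp in gap_polygons) inside <- inside | point_in_polygon(pts, gp)
    return(100 * mean(inside))
  }
  # many centers: rasterize the gap union once on the quadrature grid, then
  # average mask cells under the disc per center (identical quadrature, but
  # each grid point is classified once instead of once per center)
  xr <- range(ctrs[, 1]); yr <- range(ctrs[, 2])
  gx <- seq(xr[1] - radius_m, xr[2] + radius_m + quad_step, by = quad_step)
  gy <- seq(yr[1] - radius_m, yr[2] + radius_m + quad_step, by = quad_step)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- rep(FALSE, nrow(pts))
  for (gp in gap_polygons) {
    bb <- as_xy(gp)
    pre <- pts[, 1] >= min(bb[, 1]) & pts[, 1] <= max(bb[, 1]) &
           pts[, 2] >= min(bb[, 2]) & pts[, 2] <= max(bb[, 2])
    if (any(pre))
      inside[pre] <- inside[pre] | point_in_polygon(pts[pre, , drop = FALSE], gp)
  }
  mask <- matrix(inside, nrow = length(gx), ncol = length(gy))
  di <- round(disc$dx / quad_step); dj <- round(disc$dy / quad_step)
  vapply(seq_len(nrow(ctrs)), function(i) {
    ci <- round((ctrs[i, 1] - gx[1]) / quad_step) + 1L
    cj <- round((ctrs[i, 2] - gy[1]) / quad_step) + 1L
    100 * mean(mask[cbind(ci + di, cj + dj)])
  }, 0)
}

#' Route presence in a quadrat
#'
#' A quadrat contains a route when any network segment with at least
#' `min_weeks` weeks of use intersects the closed cell square (touching the
#' boundary, including a corner, counts).
#'
#' @param grid quadrat grid ([make_grid()]).
#' @param network a `"route_network"`.
#' @param min_weeks usage threshold (2 = habitual, 4 = high-use).
#' @param cell_m cell size (defaults to the grid's).
#' @return Integer vector of 0/1 flags parallel to `grid` rows.
#' @export
route_presence <- function(grid, network, min_weeks = 2,
                           cell_m = attr(grid, "cell_m")) {
  if (is.null(cell_m)) cell_m <- 10
  segs <- habitual_segments(network, min_weeks)
  pres <- integer(nrow(grid))
  if (!length(segs)) return(pres)
  half <- cell_m / 2
  # coarse prefilter: cell centers within half*sqrt(2) + eps of a segment
  for (s in segs) {
    xy <- s$xy
    near <- which(dist_to_path(cbind(grid$cx, grid$cy), xy) <= half * sqrt(2) + 1e-9)
    for (i in near) {
      if (pres[i] == 1L) next
      xmin <- grid$cx[i] - half; xmax <- grid$cx[i] + half
      ymin <- grid$cy[i] - half; ymax <- grid$cy[i] + half
      for (k in seq_len(nrow(xy) - 1)) {
        if (segment_intersects_rect(xy[k, 1], xy[k, 2], xy[k + 1, 1], xy[k + 1, 2],
                                    xmin, xmax, ymin, ymax)) {
          pres[i] <- 1L; break
        }
      }
    }
  }
  pres
}

#' Assemble the quadrat covariate table for one group
#'
#' Combines the grid with elevation (raw and relative to the group minimum),
#' slope, gap coverage, the food-tree density index, route presence at the
#' habitual and high-use thresholds, and core-area membership.
#'
#' @param group_id label.
#' @param home_range polygon defining the group's range (e.g. 95% isopleth).
#' @param dem a `route_dem`.
#' @param gaps list of gap polygons.
#' @param trees data.frame with `x`, `y` for the group's food trees.
#' @param network the group's `"route_network"`.
#' @param core polygon of the 50% core area, or `NULL`.
#' @param cell_m quadrat size (default 10 m).
#' @param gap_radius_m gap-buffer radius (default 25 m).
#' @param visual_radii buffer radii for the tree-density index
#'   (default `seq(5, 35, by = 5)`).
#' @param habitual_weeks,highuse_weeks route-presence thresholds (2 and 4).
#' @return data.frame of `QuadratRecord` fields.
#' @export
quadrat_table <- function(group_id, home_range, dem, gaps, trees, network,
                          core = NULL, cell_m = 10, gap_radius_m = 25,
                          visual_radii = seq(5, 35, by = 5),
                          habitual_weeks = 2, highuse_weeks = 4) {
  grid <- make_grid(home_range, cell_m)
  elev <- dem_extract(dem, cbind(grid$cx, grid$cy))
  out <- data.frame(cell_id = grid$cell_id, cx = grid$cx, cy = grid$cy,
                    group_id = group_id,
                    elevation_m = elev,
                    rel_elevation = elev - min(elev),
                    slope_deg = slope_at(dem, grid, cell_m),
                    gap_pct = gap_coverage(cbind(grid$cx, grid$cy), gaps,
                                           gap_radius_m),
                    ft_density = ft_density_index(cbind(grid$cx, grid$cy),
                                                  trees, radii = visual_radii),
                    route_ge2 = route_presence(grid, network, habitual_weeks,
                                               cell_m),
                    route_ge4 = route_presence(grid, network, highuse_weeks,
                                               cell_m))
  out$core_flag <- if (is.null(core)) 0L else
    as.integer(point_in_polygon(cbind(out$cx, out$cy), core))
  out$overlap_flag <- 0L
  attr(out, "cell_m") <- cell_m
  out
}

#' Flag quadrats used by more than one group
#'
#' Given per-group quadrat tables and the matching home-range polygons, sets
#' `overlap_flag = 1` on every quadrat whose center falls inside another
#' group's home range.
#'
#' @param quadrat_tables named list of [quadrat_table()] outputs.
#' @param home_ranges named list of polygons (same names).
#' @return The list of tables with `overlap_flag` filled in.
#' @export
flag_overlap <- function(quadrat_tables, home_ranges) {
  gids <- names(quadrat_tables)
  for (g in gids) {
    q <- quadrat_tables[[g]]
    flag <- rep(FALSE, nrow(q))
    for (other in setdiff(gids, g)) {
      flag <- flag | point_in_polygon(cbind(q$cx, q$cy), home_ranges[[other]])
    }
    quadrat_tables[[g]]$overlap_flag <- as.integer(flag)
  }
  quadrat_tables
}
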