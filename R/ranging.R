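# Kernel home-range estimation: bivariate Gaussian product-kernel density on
# a regular grid, isopleths extracted as the smallest-area density region
# holding a stated probability mass, polygons traced by contouring.

#' Reference bandwidth (href) for a bivariate Gaussian kernel
#'
#' The conventional ad-hoc rule used by kernel home-range software:
#' `h = 0.5 * (sd(x) + sd(y)) * n^(-1/6)`.
#'
#' @param pts two-column matrix of relocations.
#' @return Bandwidth in meters (kernel SD per axis).
#' @export
href_bandwidth <- function(pts) {
  pts <- as_xy(pts)
  0.5 * (stats::sd(pts[, 1]) + stats::sd(pts[, 2])) * nrow(pts)^(-1 / 6)
}

#' Kernel density home range
#'
#' Estimates a utilization distribution by a bivariate Gaussian kernel with a
#' common per-axis bandwidth, then extracts isopleths: for probability mass
#' `q`, the isopleth is the smallest-area set of grid cells containing
#' fraction `q` of the total density mass (cells sorted by density). Isopleth
#' outlines are traced with contour lines on the discretized density.
#'
#' @param points two-column matrix or data.frame of relocations (m).
#' @param bandwidth kernel SD in meters, or `"href"` (default) for the
#'   reference rule.
#' @param grid_res_m grid resolution (default 5 m).
#' @param isopleths probability masses (default home range 0.95, core 0.50).
#' @param min_points minimum relocations required (default 30).
#' @param group_id label carried through to summaries.
#' @return Object of class `"homerange"`: per-isopleth polygons (list of ring
#'   matrices), areas (ha), the density grid, thresholds and bandwidth.
#' @export
kde_home_range <- function(points, bandwidth = "href", grid_res_m = 5,
                           isopleths = c(0.5, 0.95), min_points = 30,
                           group_id = "G1") {
  pts <- as_xy(points)
  if (nrow(pts) < min_points)
    stop("too few points for a kernel home range (need >= ", min_points, ")")
  if (stats::sd(pts[, 1]) == 0 || stats::sd(pts[, 2]) == 0)
    stop("degenerate (collinear or constant) relocations")
  h <- if (identical(bandwidth, "href")) href_bandwidth(pts) else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  pad <- 3.5 * h + 2 * grid_res_m
  gx <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = grid_res_m)
  gy <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = grid_res_m)
  # density(x_i, y_j) via two dnorm matrices and one matrix product
  Ax <- outer(gx, pts[, 1], function(a, b) stats::dnorm(a, b, h))
  Ay <- outer(gy, pts[, 2], function(a, b) stats::dnorm(a, b, h))
  dens <- (Ax %*% t(Ay)) / nrow(pts)        # [x, y]
  cellmass <- dens * grid_res_m^2
  total <- sum(cellmass)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(cellmass[ord]) / total
  isopleths <- sort(isopleths)
  out <- list(group_id = group_id, bandwidth = h, grid_res_m = grid_res_m,
              gx = gx, gy = gy, density = dens, isopleths = list())
  for (q in isopleths) {
    k <- which(cum >= q)[1]
    thr <- dens[ord[k]]
    mask <- dens >= thr
    area_ha <- sum(mask) * grid_res_m^2 / 1e4
    cl <- grDevices::contourLines(gx, gy, dens, levels = thr)
    rings <- lapply(cl, function(cc) cbind(x = cc$x, y = cc$y))
    out$isopleths[[sprintf("%g", q)]] <-
      list(q = q, threshold = thr, mask = mask, area_ha = area_ha,
           polygons = rings)
  }
  class(out) <- "homerange"
  out
}

#' @export
print.homerange <- function(x, ...) {
  cat(sprintf("<homerange> group %s, bandwidth %.1f m, grid %g m\n",
              x$group_id, x$bandwidth, x$grid_res_m))
  for (iso in x$isopleths)
    cat(sprintf("  %2.0f%% isopleth: %.2f ha (%d ring%s)\n", 100 * iso$q,
                iso$area_ha, length(iso$polygons),
                if (length(iso$polygons) == 1) "" else "s"))
  invisible(x)
}

#' Extract isopleth polygons from a home range
#'
#' @param hr a `"homerange"`.
#' @param q isopleth mass (e.g. 0.95).
#' @return List of ring matrices.
#' @export
hr_isopleth <- function(hr, q = 0.95) {
  key <- sprintf("%g", q)
  if (!key %in% names(hr$isopleths)) stop("isopleth ", q, " was not computed")
  hr$isopleths[[key]]$polygons
}

#' Is a point inside a home-range isopleth?
#'
#' Evaluated on the discretized density mask (nearest grid cell), which is
#' the same definition used for isopleth areas.
#'
#' @param hr a `"homerange"`.
#' @param pts two-column matrix.
#' @param q isopleth mass.
#' @return Logical vector.
#' @export
hr_contains <- function(hr, pts, q = 0.95) {
  key <- sprintf("%g", q)
  if (!key %in% names(hr$isopleths)) stop("isopleth ", q, " was not computed")
  pts <- as_xy(pts)
  ix <- round((pts[, 1] - hr$gx[1]) / hr$grid_res_m) + 1
  iy <- round((pts[, 2] - hr$gy[1]) / hr$grid_res_m) + 1
  ok <- ix >= 1 & ix <= length(hr$gx) & iy >= 1 & iy <= length(hr$gy)
  res <- rep(FALSE, nrow(pts))
  m <- hr$isopleths[[key]]$mask
  res[ok] <- m[cbind(ix[ok], iy[ok])]
  res
}

#' Summarise home-range areas
#'
#' @param home_ranges a `"homerange"` or list of them.
#' @param q isopleth to report (default 0.95).
#' @return data.frame `group_id`, `area_ha`, `bandwidth`.
#' @export
hr_summary <- function(home_ranges, q = 0.95) {
  if (inherits(home_ranges, "homerange")) home_ranges <- list(home_ranges)
  key <- sprintf("%g", q)
  rows <- lapply(home_ranges, function(hr) {
    if (!key %in% names(hr$isopleths)) stop("isopleth ", q, " was not computed")
    a <- hr$isopleths[[key]]$area_ha
    if (!is.finite(a) || a <= 0) stop("empty isopleth polygon for group ", hr$group_id)
    data.frame(group_id = hr$group_id, area_ha = a, bandwidth = hr$bandwidth)
  })
  do.call(rbind, rows)
}

#' Area of a polygon in hectares
#'
#' @param poly ring matrix or list of rings.
#' @return Area in ha.
#' @export
polygon_area_ha <- function(poly) {
  a <- polygon_area(poly)
  if (a <= 0) stop("empty or degenerate polygon")
  a / 1e4
}
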