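# Minimal single-band regular grid ("dem" object) with ESRI ASCII I/O.
# z is a matrix with rows = y (south to north), cols = x (west to east);
# (x0, y0) is the lower-left corner of the grid, cellsize in meters.

#' Construct a regular elevation grid
#'
#' @param z numeric matrix, rows increasing northwards, columns eastwards.
#' @param x0,y0 lower-left corner (meters).
#' @param cellsize cell edge length (meters).
#' @return An object of class `"route_dem"`.
#' @export
dem_grid <- function(z, x0, y0, cellsize) {
  stopifnot(is.matrix(z), cellsize > 0)
  structure(list(z = z, x0 = x0, y0 = y0, cellsize = cellsize),
            class = "route_dem")
}

#' @export
print.route_dem <- function(x, ...) {
  cat(sprintf("<route_dem> %d x %d cells @ %g m, origin (%g, %g), z in [%g, %g]\n",
              nrow(x$z), ncol(x$z), x$cellsize, x$x0, x$y0,
              min(x$z), max(x$z)))
  invisible(x)
}

# cell-center coordinate vectors
dem_xcenters <- function(dem) dem$x0 + (seq_len(ncol(dem$z)) - 0.5) * dem$cellsize
dem_ycenters <- function(dem) dem$y0 + (seq_len(nrow(dem$z)) - 0.5) * dem$cellsize

#' Bilinear elevation lookup
#'
#' Interpolates between the four surrounding cell centers; queries outside the
#' grid of centers are clamped to the edge (constant extrapolation).
#'
#' @param dem a `route_dem`.
#' @param pts two-column matrix of query points.
#' @return Numeric vector of elevations.
#' @export
dem_extract <- function(dem, pts) {
  pts <- as_xy(pts)
  xc <- dem_xcenters(dem); yc <- dem_ycenters(dem)
  fx <- (pts[, 1] - xc[1]) / dem$cellsize
  fy <- (pts[, 2] - yc[1]) / dem$cellsize
  fx <- pmin(pmax(fx, 0), length(xc) - 1)
  fy <- pmin(pmax(fy, 0), length(yc) - 1)
  ix <- pmin(floor(fx), length(xc) - 2); ix <- pmax(ix, 0)
  iy <- pmin(floor(fy), length(yc) - 2); iy <- pmax(iy, 0)
  tx <- fx - ix; ty <- fy - iy
  if (length(xc) == 1) { ix <- 0; tx <- 0 }
  if (length(yc) == 1) { iy <- 0; ty <- 0 }
  z <- dem$z
  idx <- function(r, c) z[cbind(r + 1L, c + 1L)]
  z00 <- idx(iy, ix); z01 <- idx(iy, pmin(ix + 1, ncol(z) - 1))
  z10 <- idx(pmin(iy + 1, nrow(z) - 1), ix)
  z11 <- idx(pmin(iy + 1, nrow(z) - 1), pmin(ix + 1, ncol(z) - 1))
  z00 * (1 - tx) * (1 - ty) + z01 * tx * (1 - ty) +
    z10 * (1 - tx) * ty + z11 * tx * ty
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param dem a `route_dem`.
#' @param path output file (conventionally `.asc`).
#' @export
write_esri_ascii <- function(dem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(dem$z)),
    sprintf("nrows %d", nrow(dem$z)),
    sprintf("xllcorner %.10g", dem$x0),
    sprintf("yllcorner %.10g", dem$y0),
    sprintf("cellsize %.10g", dem$cellsize),
    "NODATA_value -9999"
  ), con)
  # ESRI ASCII stores rows north-to-south
  for (r in rev(seq_len(nrow(dem$z))))
    writeLines(paste(formatC(dem$z[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path input `.asc` file.
#' @return A `route_dem`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  z[z == hdr$nodata_value] <- NA_real_
  z <- z[rev(seq_len(nrow(z))), , drop = FALSE]   # back to south-to-north
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  dem_grid(z, x0, y0, hdr$cellsize)
}

#' Rasterised distance to a set of polylines
#'
#' Computes, on a regular grid, the distance from each cell center to the
#' nearest point of any input polyline. Used to make large Monte Carlo null
#' simulations affordable: point queries then reduce to a bilinear lookup.
#'
#' @param paths list of two-column vertex matrices.
#' @param xmin,xmax,ymin,ymax extent to cover.
#' @param cellsize grid resolution in meters (default 1).
#' @param max_dist distances are exact up to this value; cells farther from
#'   every polyline keep the value `max_dist` (default `Inf` = fully exact).
#' @return A `route_dem` whose z values are distances in meters.
#' @export
distance_raster <- function(paths, xmin, xmax, ymin, ymax, cellsize = 1,
                            max_dist = Inf) {
  xc <- seq(xmin + cellsize / 2, xmax, by = cellsize)
  yc <- seq(ymin + cellsize / 2, ymax, by = cellsize)
  px <- rep(xc, each = length(yc))
  py <- rep(yc, times = length(xc))
  bestv <- rep(if (is.finite(max_dist)) max_dist else Inf, length(px))
  for (p in paths) {
    p <- as_xy(p)
    nseg <- nrow(p) - 1
    for (k in seq_len(max(nseg, 1))) {
      a <- p[min(k, nrow(p)), ]; b <- p[min(k + 1, nrow(p)), ]
      if (is.finite(max_dist)) {
        sel <- which(px >= min(a[1], b[1]) - max_dist &
                     px <= max(a[1], b[1]) + max_dist &
                     py >= min(a[2], b[2]) - max_dist &
                     py <= max(a[2], b[2]) + max_dist)
        if (!length(sel)) next
        bestv[sel] <- pmin(bestv[sel],
                           .dist_to_segment(px[sel], py[sel],
                                            a[1], a[2], b[1], b[2]))
      } else {
        bestv <- pmin(bestv, .dist_to_segment(px, py, a[1], a[2], b[1], b[2]))
      }
    }
  }
  best <- matrix(bestv, nrow = length(yc), ncol = length(xc))
  dem_grid(best, xmin, ymin, cellsize)
}
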