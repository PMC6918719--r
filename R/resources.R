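# Food-tree interception along the route network: observed buffer counts,
# the complete-spatial-randomness Monte Carlo null, per-meter interception
# rates, the 5-35 m visibility (tree-density) index, and the Clark-Evans
# nearest-neighbour clustering statistic.

# minimum distance from points to any segment in a list of network segments
.dist_to_segments <- function(pts, seg_list) {
  best <- rep(Inf, nrow(pts))
  for (s in seg_list) {
    xy <- if (is.list(s) && !is.null(s$xy)) s$xy else s
    best <- pmin(best, dist_to_path(pts, xy))
  }
  best
}

#' Observed food-tree counts in network buffers
#'
#' For each buffer radius, counts the trees lying within that distance of any
#' habitual segment (closed threshold: a tree exactly at the radius counts;
#' each tree counts at most once per radius). Distances are exact
#' point-to-segment distances.
#'
#' @param network a `"route_network"`.
#' @param trees data.frame with `x`, `y`.
#' @param radii buffer radii in meters (default 5, 10, 15, 20).
#' @param min_weeks habitual threshold (defaults to the network's).
#' @return data.frame `group_id`, `buffer_m`, `observed_count`.
#' @export
trees_in_network_buffers <- function(network, trees, radii = c(5, 10, 15, 20),
                                     min_weeks = network$habitual_threshold) {
  segs <- habitual_segments(network, min_weeks)
  if (!length(segs)) stop("network has no habitual segments")
  d <- .dist_to_segments(as_xy(trees), segs)
  data.frame(group_id = network$group_id, buffer_m = radii,
             observed_count = vapply(radii, function(r) sum(d <= r), 0L))
}

#' Complete-spatial-randomness null for buffer counts
#'
#' Simulates `n_sims` random placements of the observed number of trees,
#' uniformly over the home range excluding canopy gaps, and counts how many
#' fall within each buffer of the habitual network. Distances (for both the
#' simulated and the observed trees, so the two sides share the same
#' discretisation) are looked up on a precomputed distance raster.
#'
#' @param trees observed trees (`x`, `y`); their count sets the simulation size.
#' @param home_range polygon to scatter within.
#' @param gaps list of gap polygons excluded from sampling.
#' @param network a `"route_network"` with habitual segments.
#' @param radii buffer radii (default 5, 10, 15, 20).
#' @param n_sims simulations (default 10000).
#' @param seed RNG seed.
#' @param min_weeks habitual threshold.
#' @param raster_res distance-raster resolution (default 1 m).
#' @param dist_rast optional precomputed distance raster (from a previous
#'   call's `"dist_rast"` attribute) to avoid rebuilding it across replicate
#'   tree sets on the same network.
#' @return data.frame `group_id`, `buffer_m`, `observed_count`, `sim_mean`,
#'   `sim_sd`, `exceedance_frac` (fraction of simulations with count >=
#'   observed). Attribute `"sim_counts"` holds the n_sims x radii count matrix.
#' @export
csr_null <- function(trees, home_range, gaps, network,
                     radii = c(5, 10, 15, 20), n_sims = 10000, seed = 1,
                     min_weeks = network$habitual_threshold, raster_res = 1,
                     dist_rast = NULL) {
  segs <- habitual_segments(network, min_weeks)
  if (!length(segs)) stop("network has no habitual segments")
  pts <- as_xy(trees)
  n_trees <- nrow(pts)
  rings <- if (is.list(home_range) && !is.data.frame(home_range)) home_range
           else list(home_range)
  allv <- do.call(rbind, lapply(rings, as_xy))
  pad <- max(radii) + 2
  dr <- dist_rast
  if (is.null(dr)) {
    # 5 m resampled segment geometry: negligible chord error at these radii,
    # five-fold fewer segment operations when rasterising
    seg5 <- lapply(segs, function(s)
      if (nrow(s$xy) > 3) resample_path(s$xy, 5, keep_vertices = FALSE)
      else s$xy)
    dr <- distance_raster(seg5,
                          min(allv[, 1]) - pad, max(allv[, 1]) + pad,
                          min(allv[, 2]) - pad, max(allv[, 2]) + pad,
                          cellsize = raster_res, max_dist = max(radii) + 2)
  }
  count_at <- function(p) {
    d <- dem_extract(dr, p)
    vapply(radii, function(r) sum(d <= r), 0L)
  }
  obs <- count_at(pts)
  sims <- local_seed(seed, {
    m <- matrix(0L, n_sims, length(radii))
    for (i in seq_len(n_sims))
      m[i, ] <- count_at(runif_in_polygon(n_trees, rings, holes = gaps))
    m
  })
  out <- data.frame(
    group_id = network$group_id, buffer_m = radii, observed_count = obs,
    sim_mean = colMeans(sims),
    sim_sd = if (n_sims > 1) apply(sims, 2, stats::sd) else NA_real_,
    exceedance_frac = vapply(seq_along(radii),
                             function(j) mean(sims[, j] >= obs[j]), 0))
  attr(out, "sim_counts") <- sims
  attr(out, "dist_rast") <- dr
  out
}

#' Food trees intercepted per meter of segment
#'
#' @param segment a network segment (list with `xy`) or a vertex matrix.
#' @param trees data.frame with `x`, `y`.
#' @param radius buffer radius (m).
#' @return Trees per meter (count within `radius` divided by segment length).
#' @export
trees_per_meter <- function(segment, trees, radius) {
  xy <- if (is.list(segment) && !is.null(segment$xy)) segment$xy else as_xy(segment)
  len <- path_length(xy)
  if (len <= 0) stop("segment length must be positive")
  sum(dist_to_path(as_xy(trees), xy) <= radius) / len
}

#' Per-segment interception rates across buffers
#'
#' One row per (habitual segment x buffer radius): the number of trees within
#' the radius divided by the segment length, with the segment's weeks-used
#' count (buffer size is carried as a control covariate into the models).
#'
#' @param network a `"route_network"`.
#' @param trees data.frame with `x`, `y`.
#' @param radii buffer radii (default 5, 10, 15, 20).
#' @param min_weeks minimum usage to include (default 1 = all segments).
#' @param min_length_m segments shorter than this are skipped (default 15).
#' @return data.frame `group_id`, `segment_id`, `weeks_used`, `length_m`,
#'   `buffer_m`, `trees_per_m`.
#' @export
segment_rates <- function(network, trees, radii = c(5, 10, 15, 20),
                          min_weeks = 1, min_length_m = 15) {
  tab <- network_segments(network)
  keep <- tab$weeks_used >= min_weeks & tab$length_m >= min_length_m
  pts <- as_xy(trees)
  rows <- list()
  for (i in which(keep)) {
    xy <- network$segments[[i]]$xy
    d <- dist_to_path(pts, xy)
    for (r in radii) {
      rows[[length(rows) + 1]] <- data.frame(
        group_id = network$group_id, segment_id = tab$segment_id[i],
        weeks_used = tab$weeks_used[i], length_m = tab$length_m[i],
        buffer_m = r, trees_per_m = sum(d <= r) / tab$length_m[i])
    }
  }
  do.call(rbind, rows)
}

#' Food-tree density (visibility) index at quadrat centers
#'
#' Concentric buffers are drawn every 5 m from the cell center out to the
#' visual detection distance (35 m); each buffer's cumulative tree count
#' (trees in smaller buffers counted again) is divided by the total trees in
#' the home range, and the buffer values are averaged. Equivalently, a tree
#' at distance `d` contributes `(number of radii >= d) / 7 / total`. Trees
#' exactly at a radius count as inside (closed threshold).
#'
#' @param cell_center `c(x, y)` or a matrix of centers.
#' @param trees_in_hr data.frame with `x`, `y`: all food trees in the group's
#'   home range (the denominator).
#' @param radii buffer radii (default `seq(5, 35, by = 5)`).
#' @return Index value(s) in `[0, 1]`.
#' @export
ft_density_index <- function(cell_center, trees_in_hr,
                             radii = seq(5, 35, by = 5)) {
  pts <- as_xy(trees_in_hr)
  if (nrow(pts) == 0) stop("no trees in home range: index undefined")
  ctrs <- if (is.matrix(cell_center) || is.data.frame(cell_center))
    as_xy(cell_center) else matrix(cell_center, 1, 2)
  total <- nrow(pts)
  vapply(seq_len(nrow(ctrs)), function(i) {
    d <- sqrt((pts[, 1] - ctrs[i, 1])^2 + (pts[, 2] - ctrs[i, 2])^2)
    sum(vapply(radii, function(r) sum(d <= r), 0L)) / length(radii) / total
  }, 0)
}

#' Clark-Evans nearest-neighbour Z statistic
#'
#' `Z = (mean observed NN distance - expected) / SE` with
#' `expected = 0.5 / sqrt(n / A)` and `SE = 0.26136 / sqrt(n^2 / A)` under
#' complete spatial randomness. Negative values indicate clustering, positive
#' values dispersion. No edge correction is applied (the standard statistic).
#'
#' @param points two-column matrix of locations.
#' @param study_area area `A` in the same squared units, or a polygon whose
#'   area is used.
#' @return List `z`, `nn_mean`, `expected`, `se`, `n`, `area`.
#' @export
nearest_neighbor_z <- function(points, study_area) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 10) stop("need at least 10 points")
  A <- if (is.numeric(study_area) && length(study_area) == 1) study_area
       else polygon_area(study_area)
  if (A <= 0) stop("study area must be positive")
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  obs <- mean(nn)
  expd <- 0.5 / sqrt(n / A)
  se <- 0.26136 / sqrt(n^2 / A)
  list(z = (obs - expd) / se, nn_mean = obs, expected = expd, se = se,
       n = n, area = A)
}
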