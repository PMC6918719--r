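# Synthetic-data generator: landscapes, tree distributions, planted route
# graphs and noisy GPS travel bouts with known ground truth, so that every
# downstream stage (home ranges, network building, enrichment tests, models)
# can be verified against planted parameters.

#' Default synthetic study configuration
#'
#' Defaults emulate the field conditions the pipeline was designed around:
#' travel bouts of mean 65.3 m (SD 57.5), daily paths of ~366 m, GPS fixes
#' every 20 m with mean radial error 6.6 m, home ranges of ~7-15 ha,
#' elevation spanning 65-264 m a.s.l., and canopy-gap coverage of ~7%.
#'
#' @param seed master seed; each generator draws from its own sub-stream.
#' @param extent named vector `c(xmin, xmax, ymin, ymax)` in meters.
#' @param n_groups number of social groups.
#' @param hr_area_ha per-group target home-range area (recycled).
#' @param elev_range elevation range (m) of the synthetic terrain.
#' @param gap_fraction proportion of the extent covered by canopy gaps.
#' @param n_trees food trees per group (recycled).
#' @param route_nodes nodes in each planted route graph.
#' @param route_fidelity probability that a travel bout follows the planted
#'   graph rather than a correlated random walk.
#' @param gps_sigma_m per-coordinate GPS noise SD; the default
#'   `6.6 * sqrt(2/pi) = 5.27` makes the mean radial fix error 6.6 m.
#' @param n_weeks sampling weeks per group.
#' @param bouts_per_day travel bouts per observation day.
#' @param days_per_week observation days per sampling week.
#' @param resample_step_m fix spacing along travel paths (m).
#' @param bout_mean_m,bout_sd_m target mean/SD of bout length (m).
#' @return A list of class `"synth_config"`.
#' @export
synthetic_config <- function(seed = 1,
                             extent = c(xmin = 0, xmax = 700, ymin = 0, ymax = 700),
                             n_groups = 5,
                             hr_area_ha = c(10.3, 7.1, 15.3, 10.6, 8.6),
                             elev_range = c(65, 264),
                             gap_fraction = 0.07,
                             n_trees = c(137, 220, 213, 227, 134),
                             route_nodes = 18,
                             route_fidelity = 0.7,
                             gps_sigma_m = 6.6 * sqrt(2 / pi),
                             n_weeks = 15,
                             bouts_per_day = 5,
                             days_per_week = 4,
                             resample_step_m = 20,
                             bout_mean_m = 65.3,
                             bout_sd_m = 57.5) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1,
            route_fidelity >= 0, route_fidelity <= 1,
            gps_sigma_m >= 0, resample_step_m > 0)
  cfg <- list(seed = seed, extent = .as_extent(extent), n_groups = n_groups,
              hr_area_ha = rep_len(hr_area_ha, n_groups),
              elev_range = elev_range, gap_fraction = gap_fraction,
              n_trees = rep_len(n_trees, n_groups),
              route_nodes = route_nodes, route_fidelity = route_fidelity,
              gps_sigma_m = gps_sigma_m, n_weeks = n_weeks,
              bouts_per_day = bouts_per_day, days_per_week = days_per_week,
              resample_step_m = resample_step_m,
              bout_mean_m = bout_mean_m, bout_sd_m = bout_sd_m)
  class(cfg) <- "synth_config"
  cfg
}

.as_extent <- function(e) {
  if (is.list(e)) e <- unlist(e)
  if (is.null(names(e)) && length(e) == 4)
    names(e) <- c("xmin", "xmax", "ymin", "ymax")
  e <- e[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(e) || e["xmax"] <= e["xmin"] || e["ymax"] <= e["ymin"])
    stop("degenerate extent: need xmin < xmax and ymin < ymax")
  e
}

#' Generate a smooth synthetic elevation model
#'
#' A Gaussian white-noise field is smoothed with a separable Gaussian filter
#' and rescaled so the terrain spans `roughness` of `elev_range`, centered at
#' the range midpoint. `roughness = 0` gives perfectly flat terrain;
#' `roughness = 1` uses the full range.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param elev_range `c(min, max)` elevation bounds (m).
#' @param roughness relief amplitude in `[0, 1]`.
#' @param seed RNG seed.
#' @param cellsize raster resolution (m), default 5.
#' @param smooth_m smoothing length scale (m), default 80.
#' @return A `route_dem`.
#' @export
generate_dem <- function(extent, elev_range = c(65, 264), roughness = 1,
                         seed = 1, cellsize = 5, smooth_m = 80) {
  e <- .as_extent(extent)
  if (roughness < 0) stop("roughness must be >= 0")
  if (roughness > 1) stop("roughness must be <= 1 (fraction of elev_range)")
  nc <- max(2L, ceiling((e["xmax"] - e["xmin"]) / cellsize))
  nr <- max(2L, ceiling((e["ymax"] - e["ymin"]) / cellsize))
  mid <- mean(elev_range)
  z <- local_seed(seed, {
    m <- matrix(stats::rnorm(nr * nc), nr, nc)
    m <- .gauss_smooth(m, smooth_m / cellsize)
    if (roughness == 0 || diff(range(m)) == 0) {
      matrix(mid, nr, nc)
    } else {
      u <- (m - min(m)) / diff(range(m))          # [0, 1]
      mid + roughness * (diff(elev_range) / 2) * (2 * u - 1)
    }
  })
  dem_grid(z, e["xmin"], e["ymin"], cellsize)
}

# separable Gaussian smoothing with replicated-edge padding
.gauss_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  k <- k / sum(k)
  sm1 <- function(M) {
    nr <- nrow(M)
    Mp <- rbind(M[rep(1, half), , drop = FALSE], M,
                M[rep(nr, half), , drop = FALSE])
    out <- matrix(0, nr, ncol(M))
    for (j in seq_along(k))
      out <- out + k[j] * Mp[j:(j + nr - 1), , drop = FALSE]
    out
  }
  t(sm1(t(sm1(m))))
}

#' Generate canopy-gap polygons
#'
#' Places `n_patches` irregular, mutually non-overlapping blob polygons whose
#' summed area equals `gap_fraction` of the extent area (exactly, by
#' construction, up to polygon discretisation).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param gap_fraction proportion of the extent to cover, in `[0, 1)`.
#' @param n_patches number of gap polygons.
#' @param seed RNG seed.
#' @return List of ring matrices (possibly empty).
#' @export
generate_gaps <- function(extent, gap_fraction = 0.07, n_patches = 8, seed = 1) {
  e <- .as_extent(extent)
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  if (gap_fraction == 0) return(list())
  A <- (e["xmax"] - e["xmin"]) * (e["ymax"] - e["ymin"])
  target <- gap_fraction * A
  local_seed(seed, {
    w <- stats::runif(n_patches, 0.5, 1.5)
    areas <- target * w / sum(w)
    radii <- sqrt(areas / pi)
    if (any(2.6 * radii > min(e["xmax"] - e["xmin"], e["ymax"] - e["ymin"])))
      stop("infeasible patch count: patches too large for the extent; ",
           "increase n_patches or shrink gap_fraction")
    centers <- matrix(NA_real_, n_patches, 2)
    for (i in seq_len(n_patches)) {
      placed <- FALSE
      for (try in 1:500) {
        cx <- stats::runif(1, e["xmin"] + 1.3 * radii[i], e["xmax"] - 1.3 * radii[i])
        cy <- stats::runif(1, e["ymin"] + 1.3 * radii[i], e["ymax"] - 1.3 * radii[i])
        if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                               (centers[seq_len(i - 1), 2] - cy)^2) >
                          1.3 * (radii[seq_len(i - 1)] + radii[i]))) {
          centers[i, ] <- c(cx, cy); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("infeasible patch count: could not place non-overlapping gaps")
    }
    lapply(seq_len(n_patches), function(i) {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      wig <- 1 + 0.18 * cos(th + stats::runif(1, 0, 2 * pi)) +
                 0.12 * cos(2 * th + stats::runif(1, 0, 2 * pi))
      ring <- cbind(x = centers[i, 1] + radii[i] * wig * cos(th),
                    y = centers[i, 2] + radii[i] * wig * sin(th))
      scl <- sqrt(areas[i] / polygon_area(ring))   # hit the target area exactly
      cbind(x = centers[i, 1] + (ring[, 1] - centers[i, 1]) * scl,
            y = centers[i, 2] + (ring[, 2] - centers[i, 2]) * scl)
    })
  })
}

#' Generate a planted route graph inside a home range
#'
#' Nodes are placed by sequential inhibition (minimum spacing), connected by a
#' minimum spanning tree plus a few short chords, and each edge is given a
#' mild random curvature so that planted routes are polylines, not chords.
#'
#' @param home_range polygon (ring matrix or list of rings).
#' @param n_nodes number of graph nodes.
#' @param seed RNG seed.
#' @param extra_edges chords added beyond the spanning tree
#'   (default `round(n_nodes / 4)`).
#' @return A list of class `"route_graph"`: `nodes` (matrix), `edges`
#'   (data.frame `from`, `to`, `length_m`), `lines` (list of polylines).
#' @export
generate_route_graph <- function(home_range, n_nodes = 18, seed = 1,
                                 extra_edges = round(n_nodes / 4)) {
  stopifnot(n_nodes >= 2)
  local_seed(seed, {
    A <- polygon_area(home_range)
    minsep <- 0.55 * sqrt(A / n_nodes)
    nodes <- matrix(NA_real_, 0, 2)
    guard <- 0
    while (nrow(nodes) < n_nodes && guard < 4000) {
      p <- runif_in_polygon(1, home_range)
      if (nrow(nodes) == 0 ||
          min(sqrt((nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2)) > minsep)
        nodes <- rbind(nodes, p)
      guard <- guard + 1
    }
    if (nrow(nodes) < n_nodes)
      nodes <- rbind(nodes, runif_in_polygon(n_nodes - nrow(nodes), home_range))
    d <- as.matrix(stats::dist(nodes))
    # Prim's MST
    n <- nrow(nodes); intree <- c(1L); edges <- NULL
    while (length(intree) < n) {
      out <- setdiff(seq_len(n), intree)
      sub <- d[intree, out, drop = FALSE]
      k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      edges <- rbind(edges, c(intree[k[1]], out[k[2]]))
      intree <- c(intree, out[k[2]])
    }
    # add short chords not already present
    have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    cand <- which(upper.tri(d), arr.ind = TRUE)
    cand <- cand[order(d[cand]), , drop = FALSE]
    added <- 0
    for (r in seq_len(nrow(cand))) {
      if (added >= extra_edges) break
      key <- paste(cand[r, 1], cand[r, 2])
      if (!key %in% have) {
        edges <- rbind(edges, cand[r, ]); have <- c(have, key); added <- added + 1
      }
    }
    lines <- lapply(seq_len(nrow(edges)), function(i) {
      a <- nodes[edges[i, 1], ]; b <- nodes[edges[i, 2], ]
      mid <- (a + b) / 2
      len <- sqrt(sum((b - a)^2))
      perp <- c(-(b - a)[2], (b - a)[1]) / max(len, 1e-9)
      bow <- stats::rnorm(1, 0, 0.06 * len)
      rbind(a, mid + perp * bow, b)
    })
    g <- list(nodes = nodes,
              edges = data.frame(from = edges[, 1], to = edges[, 2],
                                 length_m = vapply(lines, path_length, 0)),
              lines = lines)
    class(g) <- "route_graph"
    g
  })
}

#' @export
print.route_graph <- function(x, ...) {
  cat(sprintf("<route_graph> %d nodes, %d edges, total length %.0f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m)))
  invisible(x)
}

#' Assign planted weekly usage to route-graph edges
#'
#' Each edge receives a usage multiplicity drawn from `multiplicities` and a
#' random subset of that many sampling weeks; scheduled traversals then make
#' the planted weeks-used counts exact ground truth.
#'
#' @param graph a `route_graph`.
#' @param n_weeks number of sampling weeks available.
#' @param multiplicities candidate weekly usage counts.
#' @param seed RNG seed.
#' @return data.frame `edge`, `week`; attribute `"multiplicity"` holds the
#'   per-edge planted count.
#' @export
plant_usage <- function(graph, n_weeks, multiplicities = c(1, 2, 4, 7),
                        seed = 1) {
  if (max(multiplicities) > n_weeks)
    stop("multiplicities exceed the number of weeks")
  local_seed(seed, {
    ne <- nrow(graph$edges)
    mult <- multiplicities[1 + (seq_len(ne) - 1) %% length(multiplicities)]
    mult <- sample(mult)                       # random assignment, all classes used
    rows <- lapply(seq_len(ne), function(i)
      data.frame(edge = i, week = sort(sample.int(n_weeks, mult[i]))))
    out <- do.call(rbind, rows)
    attr(out, "multiplicity") <- mult
    out
  })
}

#' Generate food-tree locations
#'
#' `mode = "CSR"` scatters trees uniformly at random over the home range
#' excluding canopy gaps (complete spatial randomness, the null the
#' enrichment analysis tests against). `mode = "route_biased"` places trees
#' at exponentially distributed distances from the planted route graph
#' (rate `bias_lambda`), emulating resource enrichment along routes.
#'
#' @param home_range polygon.
#' @param gaps list of gap polygons (may be empty).
#' @param n number of trees.
#' @param mode `"CSR"` or `"route_biased"`.
#' @param bias_lambda decay rate (1/m) of tree density with distance from the
#'   graph (route_biased mode).
#' @param route_graph a `route_graph` (route_biased mode).
#' @param seed RNG seed.
#' @return data.frame `tree_id`, `x`, `y`, `species`, `dbh_cm`.
#' @export
generate_trees <- function(home_range, gaps = list(), n, mode = c("CSR", "route_biased"),
                           bias_lambda = 0.1, route_graph = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (n <= 0) stop("n must be positive")
  local_seed(seed, {
    if (mode == "CSR") {
      pts <- runif_in_polygon(n, home_range, holes = gaps)
    } else {
      if (is.null(route_graph)) stop("route_biased mode needs a route_graph")
      lens <- route_graph$edges$length_m
      cum <- cumsum(lens)
      pts <- matrix(NA_real_, 0, 2)
      guard <- 0
      while (nrow(pts) < n && guard < 400 * n) {
        t <- stats::runif(1, 0, cum[length(cum)])
        ei <- findInterval(t, c(0, cum), rightmost.closed = TRUE)
        line <- resample_path(route_graph$lines[[ei]], 1)
        pos <- t - c(0, cum)[ei]
        k <- min(nrow(line), max(1, round(pos) + 1))
        dd <- stats::rexp(1, rate = bias_lambda)
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(line[k, 1] + dd * cos(th), line[k, 2] + dd * sin(th))
        ok <- point_in_polygon(rbind(p), home_range)
        if (ok && length(gaps))
          for (g in gaps) ok <- ok && !point_in_polygon(rbind(p), g)
        if (ok) pts <- rbind(pts, p)
        guard <- guard + 1
      }
      if (nrow(pts) < n) stop("could not place route-biased trees; region too small?")
      colnames(pts) <- c("x", "y")
    }
    species <- sample(c("Poulsenia armata", "Ficus sp.", "Brosimum alicastrum",
                        "Acacia glomerosa"),
                      n, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
    data.frame(tree_id = seq_len(n), x = pts[, 1], y = pts[, 2],
               species = species,
               dbh_cm = round(10 + stats::rlnorm(n, log(18), 0.6), 1))
  })
}

# log-normal parameters matching a target mean/sd
.lnorm_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate noisy GPS travel bouts
#'
#' Two modes. `"free"` (default): each bout draws a target length from a
#' log-normal matched to the configured bout mean/SD; with probability
#' `fidelity` the bout is a non-backtracking walk along the planted route
#' graph (stopping mid-edge when the target length is reached), otherwise a
#' correlated random walk inside the home range. `"scheduled"`: every bout is
#' a full single-edge traversal following a planted week schedule
#' (see [plant_usage()]), so per-edge weeks-used counts are exact truth.
#'
#' Fixes are placed every `resample_step_m` along the true path (endpoints
#' kept) and then perturbed by isotropic Gaussian noise with per-coordinate
#' SD `gps_sigma_m`.
#'
#' @param route_graph a `route_graph` (required unless `fidelity = 0`).
#' @param fidelity probability in `[0, 1]` that a bout follows the graph.
#' @param gps_sigma_m per-coordinate GPS noise SD (m).
#' @param config a [synthetic_config()] (week/day/bout counts, fix spacing).
#' @param home_range polygon for off-graph walks (required if `fidelity < 1`).
#' @param schedule data.frame `edge`, `week` for scheduled mode.
#' @param mode `"free"` or `"scheduled"`.
#' @param group_id label stored with the fixes.
#' @param seed RNG seed.
#' @return List: `tracks` (data.frame `group_id, week_id, day_id, bout_id,
#'   fix_idx, x, y, rec_type`), `true_paths` (list of noise-free polylines,
#'   parallel to bouts), `bout_info` (data.frame with per-bout metadata).
#' @export
generate_travel_bouts <- function(route_graph = NULL, fidelity = 1,
                                  gps_sigma_m = 6.6 * sqrt(2 / pi),
                                  config = synthetic_config(),
                                  home_range = NULL, schedule = NULL,
                                  mode = c("free", "scheduled"),
                                  group_id = "G1", seed = 1) {
  mode <- match.arg(mode)
  if (fidelity < 0 || fidelity > 1) stop("fidelity must be in [0, 1]")
  if (fidelity > 0 && is.null(route_graph))
    stop("empty route_graph with fidelity > 0")
  if (fidelity < 1 && is.null(home_range))
    stop("off-graph walks need a home_range polygon")
  step <- config$resample_step_m
  lp <- .lnorm_pars(config$bout_mean_m, config$bout_sd_m)
  local_seed(seed, {
    paths <- list(); meta <- list()
    if (mode == "scheduled") {
      if (is.null(schedule)) stop("scheduled mode needs a schedule")
      for (w in sort(unique(schedule$week))) {
        ew <- schedule$edge[schedule$week == w]
        for (i in seq_along(ew)) {
          line <- route_graph$lines[[ew[i]]]
          if (stats::runif(1) < 0.5) line <- line[rev(seq_len(nrow(line))), ]
          day <- 1 + (i - 1) %% config$days_per_week
          paths[[length(paths) + 1]] <- line
          meta[[length(meta) + 1]] <- data.frame(week_id = w, day_id = day,
                                                 on_graph = TRUE, edge = ew[i])
        }
      }
    } else {
      bid <- 0
      for (w in seq_len(config$n_weeks)) for (d in seq_len(config$days_per_week))
        for (b in seq_len(config$bouts_per_day)) {
          bid <- bid + 1
          on_graph <- stats::runif(1) < fidelity
          L <- stats::rlnorm(1, lp["meanlog"], lp["sdlog"])
          L <- max(L, 5)
          line <- if (on_graph) .graph_walk(route_graph, L)
                  else .crw_walk(home_range, L, step_m = 5, turn_sd_deg = 30)
          paths[[length(paths) + 1]] <- line
          meta[[length(meta) + 1]] <- data.frame(week_id = w, day_id = d,
                                                 on_graph = on_graph, edge = NA)
        }
    }
    info <- do.call(rbind, meta)
    info$bout_id <- seq_len(nrow(info))
    info$length_m <- vapply(paths, path_length, 0)
    tracks <- do.call(rbind, lapply(seq_along(paths), function(i) {
      fx <- resample_path(paths[[i]], step, keep_vertices = FALSE)
      n <- nrow(fx)
      data.frame(group_id = group_id, week_id = info$week_id[i],
                 day_id = info$day_id[i], bout_id = i, fix_idx = seq_len(n),
                 x = fx[, 1] + stats::rnorm(n, 0, gps_sigma_m),
                 y = fx[, 2] + stats::rnorm(n, 0, gps_sigma_m),
                 rec_type = "travel")
    }))
    list(tracks = tracks, true_paths = paths, bout_info = info)
  })
}

# non-backtracking walk along the graph, stopping mid-edge at length L
.graph_walk <- function(graph, L) {
  ne <- nrow(graph$edges)
  # adjacency: edges incident to each node
  inc <- lapply(seq_len(nrow(graph$nodes)), function(v)
    which(graph$edges$from == v | graph$edges$to == v))
  node <- sample.int(nrow(graph$nodes), 1)
  prev_edge <- NA_integer_
  out <- NULL; acc <- 0
  repeat {
    cands <- inc[[node]]
    if (length(cands) > 1 && !is.na(prev_edge)) cands <- setdiff(cands, prev_edge)
    if (!length(cands)) break
    ei <- if (length(cands) == 1) cands else sample(cands, 1)
    line <- graph$lines[[ei]]
    if (graph$edges$to[ei] == node) line <- line[rev(seq_len(nrow(line))), ]
    len <- path_length(line)
    if (acc + len >= L) {
      keep <- resample_path(line, 1)
      nkeep <- max(2, min(nrow(keep), round(L - acc) + 1))
      out <- rbind(out, keep[seq_len(nkeep), ])
      break
    }
    out <- rbind(out, line)
    acc <- acc + len
    node <- if (graph$edges$to[ei] == node) graph$edges$from[ei] else graph$edges$to[ei]
    prev_edge <- ei
  }
  if (is.null(out) || nrow(out) < 2) out <- graph$lines[[sample.int(ne, 1)]]
  out
}

# correlated random walk inside a polygon (wrapped-normal turning angles)
.crw_walk <- function(poly, L, step_m = 5, turn_sd_deg = 30) {
  start <- runif_in_polygon(1, poly)
  heading <- stats::runif(1, 0, 2 * pi)
  n_steps <- max(2, ceiling(L / step_m))
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- start
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, turn_sd_deg * pi / 180)
    for (try in 1:12) {
      cand <- pts[i, ] + step_m * c(cos(heading), sin(heading))
      if (point_in_polygon(rbind(cand), poly)) break
      heading <- heading + pi + stats::rnorm(1, 0, 0.5)   # bounce back inside
    }
    pts[i + 1, ] <- cand
  }
  # trim to the exact target length
  res <- resample_path(pts, 1)
  res[seq_len(min(nrow(res), max(2, round(L) + 1))), ]
}

#' Simulate route presence on quadrats from planted effects
#'
#' Draws per-quadrat Bernoulli route presence from a logistic model: the
#' linear predictor is the sum of `true_effects` applied to the named quadrat
#' columns (interaction terms written `"a:b"` use the product of columns),
#' plus an optional per-group intercept deviation.
#'
#' @param quadrats data.frame of quadrat covariates (must contain every
#'   column named by `true_effects`, and `group_id` if `group_effects` given).
#' @param true_effects named numeric vector; name `"(Intercept)"` is the
#'   intercept.
#' @param group_effects optional named vector of per-group intercept shifts.
#' @param seed RNG seed.
#' @return Integer vector of 0/1 presences (attribute `"prob"` holds the
#'   simulated probabilities).
#' @export
simulate_route_presence <- function(quadrats, true_effects,
                                    group_effects = NULL, seed = 1) {
  if (any(!is.finite(true_effects))) stop("true_effects must be finite")
  eta <- rep(0, nrow(quadrats))
  for (nm in names(true_effects)) {
    if (nm == "(Intercept)") { eta <- eta + true_effects[[nm]]; next }
    cols <- strsplit(nm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(cols, names(quadrats))
    if (length(miss))
      stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    v <- Reduce(`*`, lapply(cols, function(cc) quadrats[[cc]]))
    eta <- eta + true_effects[[nm]] * v
  }
  if (!is.null(group_effects)) {
    if (!"group_id" %in% names(quadrats)) stop("missing covariate column(s): group_id")
    eta <- eta + group_effects[as.character(quadrats$group_id)]
  }
  p <- 1 / (1 + exp(-eta))
  y <- local_seed(seed, stats::rbinom(length(p), 1, p))
  attr(y, "prob") <- p
  y
}

#' Generate a complete synthetic study
#'
#' Builds terrain, canopy gaps, per-group planted home ranges (overlapping
#' discs, as for neighbouring groups), route graphs with planted weekly usage,
#' food trees, scan fixes and noisy travel-bout fixes, all from one master
#' seed with per-component RNG streams.
#'
#' @param config a [synthetic_config()].
#' @param tree_mode `"CSR"` or `"route_biased"` (see [generate_trees()]).
#' @param bias_lambda enrichment decay rate for route_biased trees.
#' @param bout_mode `"free"` or `"scheduled"` (see [generate_travel_bouts()]).
#' @param multiplicities planted weekly usage classes for scheduled mode.
#' @return A list of class `"synth_study"`: `config`, `dem`, `gaps`,
#'   `groups` (per-group list with `hr_poly`, `graph`, `schedule`, `trees`),
#'   `tracks` (all fixes, scan + travel), `trees` (all trees with group_id),
#'   `truth` (planted parameters).
#' @export
synth_study <- function(config = synthetic_config(),
                        tree_mode = "CSR", bias_lambda = 0.1,
                        bout_mode = "free",
                        multiplicities = c(1, 2, 4, 7)) {
  e <- config$extent
  dem <- generate_dem(e, config$elev_range, roughness = 1,
                      seed = module_seed(config$seed, "dem"))
  gaps <- generate_gaps(e, config$gap_fraction, seed = module_seed(config$seed, "gaps"))
  # place home-range discs on a ring around the extent center so neighbours
  # overlap slightly (intergroup overlap is a model covariate)
  cx <- mean(e[c("xmin", "xmax")]); cy <- mean(e[c("ymin", "ymax")])
  radii <- sqrt(config$hr_area_ha * 1e4 / pi)
  k <- config$n_groups
  ring_r <- if (k == 1) 0 else max(radii) * 1.35
  groups <- list()
  tracks_all <- list(); trees_all <- list()
  for (g in seq_len(k)) {
    th <- 2 * pi * (g - 1) / max(k, 1)
    ctr <- c(cx + ring_r * cos(th), cy + ring_r * sin(th))
    r <- radii[g]
    circ <- seq(0, 2 * pi, length.out = 65)[-65]
    hr <- cbind(x = ctr[1] + r * cos(circ), y = ctr[2] + r * sin(circ))
    gid <- sprintf("G%d", g)
    graph <- generate_route_graph(hr, config$route_nodes,
                                  seed = module_seed(config$seed, "routes") + g)
    sched <- if (bout_mode == "scheduled")
      plant_usage(graph, config$n_weeks, multiplicities,
                  seed = module_seed(config$seed, "routes") + 50 + g)
    else NULL
    trees <- generate_trees(hr, gaps, config$n_trees[g], mode = tree_mode,
                            bias_lambda = bias_lambda, route_graph = graph,
                            seed = module_seed(config$seed, "trees") + g)
    trees$group_id <- gid
    bouts <- generate_travel_bouts(graph, config$route_fidelity,
                                   config$gps_sigma_m, config,
                                   home_range = hr,
                                   schedule = sched, mode = bout_mode,
                                   group_id = gid,
                                   seed = module_seed(config$seed, "bouts") + g)
    # scan fixes: uniform over the home range shrunk toward its centroid, so
    # that the 95% KDE isopleth (which a Gaussian kernel inflates outward by
    # roughly one bandwidth) lands on the planted home-range area
    nscan <- max(300, 40 * config$days_per_week * min(config$n_weeks, 12))
    scans <- local_seed(module_seed(config$seed, "scans") + g, {
      p <- runif_in_polygon(nscan, scale_polygon(hr, 0.90))
      data.frame(group_id = gid, week_id = NA, day_id = NA, bout_id = NA,
                 fix_idx = seq_len(nscan), x = p[, 1], y = p[, 2],
                 rec_type = "scan")
    })
    groups[[gid]] <- list(group_id = gid, hr_poly = hr, graph = graph,
                          schedule = sched, trees = trees,
                          bouts = bouts$bout_info, true_paths = bouts$true_paths)
    tracks_all[[length(tracks_all) + 1]] <- rbind(scans, bouts$tracks)
    trees_all[[length(trees_all) + 1]] <- trees
  }
  out <- list(config = config, dem = dem, gaps = gaps, groups = groups,
              tracks = do.call(rbind, tracks_all),
              trees = do.call(rbind, trees_all),
              truth = list(tree_mode = tree_mode, bias_lambda = bias_lambda,
                           bout_mode = bout_mode,
                           multiplicities = multiplicities))
  class(out) <- "synth_study"
  out
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d groups, %d track fixes, %d trees, %d gaps\n",
              length(x$groups), nrow(x$tracks), nrow(x$trees), length(x$gaps)))
  invisible(x)
}
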