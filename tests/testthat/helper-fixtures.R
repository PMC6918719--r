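# Shared fixtures and independent oracles, all built in code.

# closed circle polygon
circle_poly <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# a small wiggly random path: random-walk headings, `len` meters at 5 m steps
random_path <- function(len = 60, start = c(0, 0), turn_sd = 25) {
  n <- max(2, ceiling(len / 5))
  heading <- runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n + 1, 2)
  pts[1, ] <- start
  for (i in seq_len(n)) {
    heading <- heading + rnorm(1, 0, turn_sd * pi / 180)
    pts[i + 1, ] <- pts[i, ] + 5 * c(cos(heading), sin(heading))
  }
  pts
}

# independent brute-force matcher implementing the same matching definition
# as shared_segments, written with plain loops and its own bearing code
brute_force_match <- function(A1, B1, buffer_m = 10, min_overlap_m = 15,
                              max_dev_deg = 45, window_m = 10) {
  sA <- attr(A1, "s"); sB <- attr(B1, "s")
  bearing_at <- function(P, s, i) {
    # last vertex at or before s-w/2; first vertex at or after s+w/2
    lo <- s[i] - window_m / 2; hi <- s[i] + window_m / 2
    i1 <- 1; while (i1 < length(s) && s[i1 + 1] <= lo) i1 <- i1 + 1
    i2 <- length(s); while (i2 > 1 && s[i2 - 1] >= hi - 1e-9) i2 <- i2 - 1
    if (i2 <= i1) { i1 <- max(1, i - 1); i2 <- min(length(s), i + 1) }
    (atan2(P[i2, 2] - P[i1, 2], P[i2, 1] - P[i1, 1]) * 180 / pi) %% 180
  }
  nA <- nrow(A1)
  matched <- logical(nA)
  for (i in seq_len(nA)) {
    best <- Inf; bj <- 1
    for (j in seq_len(nrow(B1))) {
      dd <- sqrt((A1[i, 1] - B1[j, 1])^2 + (A1[i, 2] - B1[j, 2])^2)
      if (dd < best) { best <- dd; bj <- j }
    }
    if (best > buffer_m) next
    da <- bearing_at(A1, sA, i); db <- bearing_at(B1, sB, bj)
    dv <- abs(da - db) %% 180
    matched[i] <- min(dv, 180 - dv) <= max_dev_deg
  }
  # qualified runs by arc length
  out <- logical(nA)
  i <- 1
  while (i <= nA) {
    if (!matched[i]) { i <- i + 1; next }
    j <- i
    while (j < nA && matched[j + 1]) j <- j + 1
    if (sA[j] - sA[i] >= min_overlap_m - 1e-9) out[i:j] <- TRUE
    i <- j + 1
  }
  out
}

# per-tree-weight closed form for the visibility index: a tree at distance d
# contributes (#radii >= d) / (#radii) / total
ftd_oracle <- function(center, trees, radii = seq(5, 35, by = 5)) {
  d <- sqrt((trees$x - center[1])^2 + (trees$y - center[2])^2)
  w <- vapply(d, function(dd) sum(radii >= dd), 0L)
  sum(w) / length(radii) / nrow(trees)
}

# tiny planted scenario reused by network tests: circle home range + graph
planted_scenario <- function(seed, n_weeks = 10, mult = c(1, 2, 4, 7),
                             hr_r = 180, nodes = 18) {
  hr <- circle_poly(250, 250, hr_r)
  gr <- generate_route_graph(hr, nodes, seed = seed)
  sch <- plant_usage(gr, n_weeks, mult, seed = seed + 100)
  list(hr = hr, graph = gr, schedule = sch,
       mult = attr(sch, "multiplicity"))
}
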