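test_that("generate_dem honours range, flatness and determinism", {
  ext <- c(0, 700, 0, 700)
  flat <- generate_dem(ext, c(65, 264), roughness = 0, seed = 4)
  expect_true(all(flat$z == mean(c(65, 264))))

  d1 <- generate_dem(ext, c(65, 264), roughness = 1, seed = 9)
  expect_gte(min(d1$z), 65)
  expect_lte(max(d1$z), 264)
  d2 <- generate_dem(ext, c(65, 264), roughness = 1, seed = 9)
  expect_identical(d1$z, d2$z)
  expect_error(generate_dem(c(0, 0, 0, 10)), "degenerate")
})

test_that("generate_gaps hits the target coverage with disjoint patches", {
  expect_length(generate_gaps(c(0, 700, 0, 700), 0), 0)
  ext <- c(0, sqrt(50e4), 0, sqrt(50e4) * 10)   # 50 ha
  ext <- c(0, 1000, 0, 500)                     # 50 ha
  g <- generate_gaps(ext, 0.07, n_patches = 8, seed = 2)
  A <- sum(vapply(g, polygon_area, 0))
  expect_gt(A / 1e4, 3.5 * 0.8)
  expect_lt(A / 1e4, 3.5 * 1.2)
  # containment and pairwise disjointness (so summed area = union area)
  for (i in seq_along(g)) {
    expect_true(all(g[[i]][, 1] >= 0 & g[[i]][, 1] <= 1000))
    expect_true(all(g[[i]][, 2] >= 0 & g[[i]][, 2] <= 500))
    for (j in seq_along(g)) if (j != i)
      expect_false(any(point_in_polygon(g[[i]], g[[j]])))
  }
  expect_error(generate_gaps(c(0, 60, 0, 60), 0.9, n_patches = 1),
               "infeasible")
})

test_that("CSR trees fill the range without clustering; biased trees hug routes", {
  hr <- circle_poly(250, 250, 180)
  gaps <- list(circle_poly(320, 250, 40))
  tr <- generate_trees(hr, gaps, 137, "CSR", seed = 7)
  expect_equal(nrow(tr), 137)
  expect_true(all(point_in_polygon(cbind(tr$x, tr$y), hr)))
  expect_false(any(point_in_polygon(cbind(tr$x, tr$y), gaps[[1]])))
  z <- nearest_neighbor_z(cbind(tr$x, tr$y), polygon_area(hr))
  expect_gt(z$z, -2)   # not significantly clustered

  gr <- generate_route_graph(hr, 15, seed = 3)
  glines <- lapply(gr$lines, identity)
  tight <- generate_trees(hr, list(), 40, "route_biased", bias_lambda = 1e3,
                          route_graph = gr, seed = 5)
  d_tight <- apply(cbind(tight$x, tight$y), 1, function(p)
    min(vapply(glines, function(l) min(dist_to_path(rbind(p), l)), 0)))
  expect_lt(max(d_tight), 0.5)

  # moderate bias: mean distance to graph below the CSR mean, across seeds
  wins <- 0
  for (s in 1:15) {
    bi <- generate_trees(hr, list(), 30, "route_biased", bias_lambda = 0.08,
                         route_graph = gr, seed = 1000 + s)
    cs <- generate_trees(hr, list(), 30, "CSR", seed = 2000 + s)
    dist_of <- function(tt) mean(apply(cbind(tt$x, tt$y), 1, function(p)
      min(vapply(glines, function(l) min(dist_to_path(rbind(p), l)), 0))))
    if (dist_of(bi) < dist_of(cs)) wins <- wins + 1
  }
  expect_gte(wins, 13)
})

test_that("travel bouts follow the graph at full fidelity and match the length target", {
  sc <- planted_scenario(5)
  cfg <- synthetic_config(n_weeks = 10)
  b <- generate_travel_bouts(sc$graph, fidelity = 1, gps_sigma_m = 0,
                             config = cfg, schedule = sc$schedule,
                             mode = "scheduled", seed = 4)
  d <- vapply(seq_len(nrow(b$tracks)), function(i)
    min(vapply(sc$graph$lines, function(l)
      dist_to_path(cbind(b$tracks$x[i], b$tracks$y[i]), l), 0)), 0)
  expect_lt(max(d), 1e-6)

  expect_error(generate_travel_bouts(NULL, fidelity = 1), "route_graph")
  expect_error(generate_travel_bouts(sc$graph, fidelity = 0.5,
                                     config = cfg), "home_range")

  # free mode: grand mean bout length near the 65.3 m target
  cfg2 <- synthetic_config(n_weeks = 17, days_per_week = 4, bouts_per_day = 15)
  bf <- generate_travel_bouts(sc$graph, fidelity = 0.7, gps_sigma_m = 5.27,
                              config = cfg2, home_range = sc$hr,
                              mode = "free", seed = 21)
  expect_gte(nrow(bf$bout_info), 1000)
  expect_lt(abs(mean(bf$bout_info$length_m) - 65.3), 10)
})

test_that("GPS noise matches the mean radial error target", {
  sc <- planted_scenario(2)
  cfg <- synthetic_config(n_weeks = 10)
  sig <- 6.6 * sqrt(2 / pi)
  b <- generate_travel_bouts(sc$graph, 1, gps_sigma_m = sig, config = cfg,
                             schedule = sc$schedule, mode = "scheduled",
                             seed = 8)
  b0 <- generate_travel_bouts(sc$graph, 1, gps_sigma_m = 0, config = cfg,
                              schedule = sc$schedule, mode = "scheduled",
                              seed = 8)
  err <- sqrt((b$tracks$x - b0$tracks$x)^2 + (b$tracks$y - b0$tracks$y)^2)
  expect_lt(abs(mean(err) - 6.6), 0.6)
})

test_that("simulate_route_presence is calibrated, monotone and reproducible", {
  set.seed(2)
  q <- data.frame(group_id = rep(c("a", "b"), each = 5000),
                  ft_density = runif(10000), gap_pct = runif(10000, 0, 40))
  y0 <- simulate_route_presence(q, c("(Intercept)" = 0), seed = 3)
  expect_lt(abs(mean(y0) - 0.5), 0.03)

  y1 <- simulate_route_presence(q, c("(Intercept)" = -1, ft_density = 0.9),
                                seed = 3)
  dec <- cut(q$ft_density, quantile(q$ft_density, 0:10 / 10),
             include.lowest = TRUE)
  rates <- tapply(y1, dec, mean)
  expect_gt(suppressWarnings(cor(seq_along(rates), rates,
                                 method = "spearman")), 0.9)

  expect_identical(simulate_route_presence(q, c(ft_density = 1), seed = 9),
                   simulate_route_presence(q, c(ft_density = 1), seed = 9))
  expect_error(simulate_route_presence(q, c(nope = 1), seed = 1), "nope")
})

test_that("synthetic studies are bit-reproducible from the master seed", {
  cfg <- synthetic_config(seed = 42, n_groups = 2, hr_area_ha = c(7, 8),
                          n_trees = 60, n_weeks = 4, bouts_per_day = 2)
  s1 <- synth_study(cfg)
  s2 <- synth_study(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$trees, s2$trees)
  expect_identical(s1$dem$z, s2$dem$z)
  # geometry containment: trees inside their group's planted range, not in gaps
  for (g in s1$groups) {
    expect_true(all(point_in_polygon(cbind(g$trees$x, g$trees$y), g$hr_poly)))
    for (gp in s1$gaps)
      expect_false(any(point_in_polygon(cbind(g$trees$x, g$trees$y), gp)))
  }
})
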