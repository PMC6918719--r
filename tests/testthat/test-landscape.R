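square_poly <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))

test_that("make_grid tiles the home range with 10 m quadrats", {
  g <- make_grid(square_poly, 10)
  expect_equal(nrow(g), 100)
  expect_equal(nrow(g) * 100, 1e4)   # cells tile the square exactly
  expect_true(all(g$cx %% 10 == 5 & g$cy %% 10 == 5))
  expect_error(make_grid(cbind(x = c(0, 1), y = c(0, 0))), "degenerate")
})

test_that("slope matches the inclined-plane oracle and is flat on flat ground", {
  z <- outer(seq(5, 995, 10), seq(5, 995, 10), function(y, x) 0.5 * x)
  dem <- dem_grid(z, 0, 0, 10)
  poly <- cbind(x = c(100, 300, 300, 100), y = c(100, 100, 300, 300))
  g <- make_grid(poly, 10)
  s <- slope_at(dem, g)
  expect_equal(s, rep(atan(0.5) * 180 / pi, nrow(g)), tolerance = 1e-6)

  flat <- dem_grid(matrix(120, 100, 100), 0, 0, 10)
  expect_equal(max(slope_at(flat, g)), 0)

  g1 <- g[1, ]
  attr(g1, "cell_m") <- 10
  expect_error(slope_at(dem, g1), "no adjacent")
})

test_that("gap coverage: empty, total, half-plane and translation invariance", {
  expect_equal(gap_coverage(c(0, 0), list()), 0)
  big <- cbind(x = c(-500, 500, 500, -500), y = c(-500, -500, 500, 500))
  expect_equal(gap_coverage(c(0, 0), list(big)), 100)
  half <- cbind(x = c(-500, 500, 500, -500), y = c(-500, -500, 0, 0))
  expect_lt(abs(gap_coverage(c(0, 0), list(half)) - 50), 0.5)

  set.seed(3)
  gap <- circle_poly(30, 10, 18)
  v1 <- gap_coverage(c(20, 15), list(gap))
  shift <- c(1234, -567)
  gap2 <- cbind(gap[, 1] + shift[1], gap[, 2] + shift[2])
  v2 <- gap_coverage(c(20 + shift[1], 15 + shift[2]), list(gap2))
  expect_equal(v1, v2, tolerance = 0.5)

  # vectorised centers agree with one-at-a-time quadrature
  ctrs <- cbind(seq(0, 40, 10), seq(0, 40, 10))
  many <- gap_coverage(ctrs, list(gap))
  single <- vapply(seq_len(nrow(ctrs)), function(i)
    gap_coverage(ctrs[i, ], list(gap)), 0)
  expect_equal(many, single, tolerance = 0.75)
})

test_that("route presence thresholds are monotone and corner contact counts", {
  seg_line <- resample_path(cbind(c(0, 100), c(15, 15)), 1)
  net <- build_route_network(lapply(1:2, function(w) list(seg_line)))
  g <- make_grid(square_poly, 10)
  p2 <- route_presence(g, net, min_weeks = 2)
  p4 <- route_presence(g, net, min_weeks = 4)
  crossed <- g$cy > 10 & g$cy < 20
  expect_true(all(p2[crossed] == 1))
  expect_true(all(p4 == 0))
  expect_true(all(p2 >= p4))   # ge4 implies ge2

  # segment touching only a cell corner still counts (closed boundary)
  corner <- resample_path(cbind(c(10, 30), c(30, 10)), 1)
  netc <- build_route_network(lapply(1:2, function(w) list(corner)))
  gc1 <- data.frame(cell_id = 1, cx = 15, cy = 15, row = 2, col = 2)
  attr(gc1, "cell_m") <- 10
  expect_equal(route_presence(gc1, netc, min_weeks = 2), 1L)
})

test_that("quadrat table assembles covariates with the right invariants", {
  set.seed(8)
  dem <- generate_dem(c(0, 400, 0, 400), c(65, 264), seed = 2)
  gaps <- list(circle_poly(120, 140, 30))
  hr <- circle_poly(200, 200, 120)
  gr <- generate_route_graph(hr, 10, seed = 4)
  sch <- plant_usage(gr, 6, c(2, 4), seed = 5)
  b <- generate_travel_bouts(gr, 1, 5.27, synthetic_config(n_weeks = 6),
                             schedule = sch, mode = "scheduled", seed = 6)
  net <- build_group_network(b$tracks)
  trees <- generate_trees(hr, gaps, 80, "CSR", seed = 7)
  q <- quadrat_table("G1", hr, dem, gaps, trees, net,
                     core = circle_poly(200, 200, 60))
  expect_true(all(q$gap_pct >= 0 & q$gap_pct <= 100))
  expect_true(all(q$slope_deg >= 0 & q$slope_deg < 90))
  expect_true(all(q$ft_density >= 0 & q$ft_density <= 1))
  expect_true(all(q$route_ge2 >= q$route_ge4))
  expect_true(all(q$rel_elevation >= 0))
  expect_equal(min(q$rel_elevation), 0)
  core_cells <- q$core_flag == 1
  expect_true(all(sqrt((q$cx[core_cells] - 200)^2 +
                       (q$cy[core_cells] - 200)^2) <= 61))

  # overlap flags: duplicate table under two names, shifted ranges overlap
  hr2 <- circle_poly(280, 200, 120)
  q2 <- q; q2$group_id <- "G2"
  flagged <- flag_overlap(list(G1 = q, G2 = q2),
                          list(G1 = hr, G2 = hr2))
  expect_true(any(flagged$G1$overlap_flag == 1))
  expect_true(any(flagged$G1$overlap_flag == 0))
})
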