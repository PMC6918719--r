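two_week_net <- function(line) {
  build_route_network(lapply(1:2, function(w) list(line)))
}

test_that("network buffer counts respect distance thresholds and nesting", {
  net <- two_week_net(cbind(c(0, 100), c(0, 0)))
  trees <- data.frame(x = c(50, 50, 200), y = c(0, 12, 0))
  tab <- trees_in_network_buffers(net, trees)
  expect_equal(tab$observed_count[tab$buffer_m == 5], 1)    # on the segment
  expect_equal(tab$observed_count[tab$buffer_m == 10], 1)
  expect_equal(tab$observed_count[tab$buffer_m == 15], 2)   # 12 m tree joins
  expect_equal(tab$observed_count[tab$buffer_m == 20], 2)
  expect_true(all(diff(tab$observed_count) >= 0))

  set.seed(9)
  rtrees <- data.frame(x = runif(100, -30, 130), y = runif(100, -40, 40))
  rt <- trees_in_network_buffers(net, rtrees)
  expect_true(all(diff(rt$observed_count) >= 0))
})

test_that("trees_per_meter matches the arithmetic and scales with density", {
  seg <- cbind(c(0, 100), c(0, 0))
  trees7 <- data.frame(x = seq(10, 90, length.out = 7), y = 0)
  expect_equal(trees_per_meter(seg, trees7, 10), 0.07)
  expect_equal(trees_per_meter(seg, data.frame(x = 500, y = 500), 10), 0)
  expect_error(trees_per_meter(cbind(c(0, 0), c(0, 0)), trees7, 10), "length")

  # doubling CSR density doubles the expected rate
  set.seed(10)
  rate_at <- function(n) {
    mean(replicate(40, {
      tt <- data.frame(x = runif(n, -50, 150), y = runif(n, -100, 100))
      trees_per_meter(seg, tt, 10)
    }))
  }
  expect_lt(abs(rate_at(240) / rate_at(120) - 2), 0.2)
})

test_that("visibility index equals its per-tree closed form everywhere", {
  expect_equal(ft_density_index(c(0, 0),
                                data.frame(x = rep(100, 5), y = 0)), 0)
  expect_error(ft_density_index(c(0, 0), data.frame(x = numeric(0),
                                                    y = numeric(0))), "trees")
  set.seed(12)
  for (i in 1:100) {
    trees <- data.frame(x = runif(sample(3:40, 1), -60, 60),
                        y = runif(1, -60, 60) + rnorm(1))
    trees <- data.frame(x = runif(nrow(trees), -60, 60),
                        y = runif(nrow(trees), -60, 60))
    ctr <- runif(2, -20, 20)
    expect_equal(ft_density_index(ctr, trees), ftd_oracle(ctr, trees),
                 tolerance = 1e-12)
  }
  # adding a tree within visual range never decreases the numerator sum
  base <- data.frame(x = runif(20, -60, 60), y = runif(20, -60, 60))
  v0 <- ft_density_index(c(0, 0), base) * 20       # un-normalised numerator
  v1 <- ft_density_index(c(0, 0), rbind(base, data.frame(x = 3, y = 0))) * 21
  expect_gte(v1, v0)
})

test_that("CSR null flags planted enrichment and degrades gracefully", {
  set.seed(14)
  hr <- circle_poly(250, 250, 150)
  gr <- generate_route_graph(hr, 12, seed = 2)
  sch <- plant_usage(gr, 6, c(2, 4), seed = 3)
  b <- generate_travel_bouts(gr, 1, 0, synthetic_config(n_weeks = 6),
                             schedule = sch, mode = "scheduled", seed = 4)
  net <- build_group_network(b$tracks)
  planted <- generate_trees(hr, list(), 100, "route_biased",
                            bias_lambda = 1e3, route_graph = gr, seed = 5)
  tab <- csr_null(planted, hr, list(), net, n_sims = 400, seed = 6)
  expect_true(all(tab$exceedance_frac <= 0.05))
  expect_true(all(diff(tab$observed_count) >= 0))

  one <- csr_null(planted, hr, list(), net, n_sims = 1, seed = 7,
                  dist_rast = attr(tab, "dist_rast"))
  expect_true(all(is.na(one$sim_sd)))
  expect_equal(nrow(one), 4)
})

test_that("Clark-Evans Z separates lattice, clumped and random patterns", {
  lat <- as.matrix(expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10)))
  zl <- nearest_neighbor_z(lat, 100 * 100)
  expect_gt(zl$z, 0)

  set.seed(15)
  clump <- cbind(rnorm(50, 50, 1), rnorm(50, 50, 1))
  zc <- nearest_neighbor_z(clump, 100 * 100)
  expect_lt(zc$z, -5)

  # CSR calibration: unit variance, plus the well-known positive boundary
  # bias of the uncorrected statistic (points near the window edge have
  # inflated nearest-neighbour distances; ~ +0.8 Z units at this n and area)
  zs <- replicate(400, {
    p <- cbind(runif(60, 0, 100), runif(60, 0, 100))
    nearest_neighbor_z(p, 1e4)$z
  })
  expect_gt(mean(zs), 0)
  expect_lt(mean(zs), 1.5)
  expect_lt(abs(sd(zs) - 1), 0.25)
  expect_error(nearest_neighbor_z(lat[1:5, ], 100), "at least 10")
})
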