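r1 <- function(xy) resample_path(xy, 1)

test_that("shared_segments implements the buffer/overlap/bearing rule", {
  A <- r1(cbind(c(0, 100), c(0, 0)))
  # identical lines: one full-length shared segment
  s <- shared_segments(A, r1(cbind(c(0, 100), c(0, 0))))
  expect_length(s, 1)
  expect_lt(abs(s[[1]]$length_m - 100), 1)

  # parallel at 5 m: shared (within buffer, parallel bearings)
  s <- shared_segments(A, r1(cbind(c(0, 100), c(5, 5))))
  expect_length(s, 1)
  expect_gte(s[[1]]$length_m, 15)

  # parallel at 12 m: outside the 10 m buffer
  expect_length(shared_segments(A, r1(cbind(c(0, 100), c(12, 12)))), 0)

  # perpendicular crossing: bearing rule rejects
  expect_length(shared_segments(A, r1(cbind(c(50, 50), c(-50, 50)))), 0)

  # anti-parallel travel matches (bearings mod 180)
  s <- shared_segments(A, r1(cbind(c(100, 0), c(2, 2))))
  expect_length(s, 1)

  # matched run shorter than 15 m does not qualify: a 4 m stub at 9 m
  # lateral offset yields only ~12.7 m of A within the 10 m buffer
  expect_length(shared_segments(A, r1(cbind(c(48, 52), c(9, 9)))), 0)

  expect_error(shared_segments(cbind(c(0, 100), c(0, 0)), A), "resampled")
})

test_that("shared_segments equals the brute-force matcher on random pairs", {
  set.seed(77)
  for (i in 1:25) {
    A <- r1(random_path(runif(1, 30, 80)))
    B <- if (runif(1) < 0.5) {
      r1(random_path(runif(1, 30, 80), start = runif(2, -20, 20)))
    } else {   # jittered copy so overlap actually occurs
      p <- A[seq(1, nrow(A), by = 5), ] + rnorm(2 * length(seq(1, nrow(A), by = 5)), 0, 3)
      r1(p)
    }
    got <- attr(shared_segments(A, B), "mask")
    want <- brute_force_match(A, B)
    expect_identical(got, want)
  }
})

test_that("weekly deduplication keeps one copy of repeated geometry", {
  A <- cbind(c(0, 100), c(0, 0))
  wk <- build_weekly_paths(list(A, A), day_ids = c(1, 2))
  expect_length(wk, 1)

  B <- cbind(c(0, 100), c(200, 200))
  wk <- build_weekly_paths(list(A, B), day_ids = c(1, 2))
  expect_length(wk, 2)

  # partial overlap: the shared stretch is kept once. C runs 60..160 and its
  # 60..110 portion lies within 10 m of A (the buffer reaches past A's end),
  # so the retained union is ~100 + ~50, not 200
  C <- cbind(c(60, 160), c(0, 0))
  wk <- build_weekly_paths(list(A, C), day_ids = c(1, 2))
  tot <- sum(vapply(wk, function(l) max(l$s), 0))
  expect_gt(tot, 145)
  expect_lt(tot, 155)

  expect_error(build_weekly_paths(list(A, B), day_ids = c(1, 2),
                                  week_ids = c(1, 2)), "multiple weeks")
})

test_that("route network counts distinct weeks of use", {
  A <- cbind(c(0, 100), c(0, 0))
  wk4 <- lapply(1:4, function(w) list(A))
  net <- build_route_network(wk4)
  tab <- network_segments(net)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$weeks_used, 4)

  # disjoint weeks: everything single-use, habitual network empty
  wk3 <- list(list(cbind(c(0, 50), c(0, 0))),
              list(cbind(c(0, 50), c(100, 100))),
              list(cbind(c(0, 50), c(200, 200))))
  net <- build_route_network(wk3)
  tab <- network_segments(net)
  expect_true(all(tab$weeks_used == 1))
  expect_equal(network_summary(net)$habitual_m, 0)
  expect_length(habitual_segments(net), 0)
})

test_that("network length is partitioned and weeks_used is bounded", {
  set.seed(55)
  sc <- planted_scenario(3, n_weeks = 6, mult = c(1, 2, 4))
  b <- generate_travel_bouts(sc$graph, 1, gps_sigma_m = 5.27,
                             config = synthetic_config(n_weeks = 6),
                             schedule = sc$schedule, mode = "scheduled",
                             seed = 12)
  net <- build_group_network(b$tracks)
  tab <- network_segments(net)
  expect_true(all(tab$weeks_used >= 1 & tab$weeks_used <= 6))
  s <- network_summary(net)
  nonhab <- sum(tab$length_m[tab$weeks_used < net$habitual_threshold])
  expect_equal(s$habitual_m + nonhab, s$total_m, tolerance = 0.01 * s$total_m)
})

test_that("bout coverage reflects route fidelity", {
  sc <- planted_scenario(6, n_weeks = 8, mult = c(2, 4))
  cfg <- synthetic_config(n_weeks = 8)
  b <- generate_travel_bouts(sc$graph, 1, gps_sigma_m = 5.27, config = cfg,
                             schedule = sc$schedule, mode = "scheduled",
                             seed = 3)
  net <- build_group_network(b$tracks)
  bl <- tracks_to_bouts(b$tracks)$lines
  cov <- network_coverage(bl, net)
  expect_gte(as.numeric(cov), 0.9)

  empty <- build_route_network(list(list(cbind(c(0, 30), c(0, 0)))))
  expect_equal(as.numeric(network_coverage(bl, empty, min_weeks = 2)), 0)
})
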