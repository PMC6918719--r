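test_that("kernel home range matches the closed-form Gaussian oracle", {
  set.seed(31)
  pts <- cbind(rnorm(500, 0, 20) + 300, rnorm(500, 0, 20) + 300)
  hr <- kde_home_range(pts, grid_res_m = 2)
  h <- hr$bandwidth
  # N(0, s^2 I) smoothed by N(0, h^2 I) has 95% mass in a disc of area
  # pi * chi2_{0.95,2} * (s^2 + h^2)
  a_true <- pi * qchisq(0.95, 2) * (400 + h^2) / 1e4
  expect_lt(abs(hr$isopleths[["0.95"]]$area_ha / a_true - 1), 0.15)
})

test_that("isopleths contain their stated mass and nest correctly", {
  set.seed(32)
  pts <- cbind(rnorm(400, 0, 15), rnorm(400, 0, 15))
  hr <- kde_home_range(pts, grid_res_m = 1)
  cellmass <- hr$density * hr$grid_res_m^2
  frac95 <- sum(cellmass[hr$isopleths[["0.95"]]$mask]) / sum(cellmass)
  expect_gte(frac95, 0.95)
  expect_lte(frac95, 0.96)
  expect_true(all(hr$isopleths[["0.95"]]$mask[hr$isopleths[["0.5"]]$mask]))
  # monotone area in isopleth mass
  hr3 <- kde_home_range(pts, grid_res_m = 2, isopleths = c(0.2, 0.5, 0.8, 0.95))
  areas <- vapply(hr3$isopleths, `[[`, 0, "area_ha")
  expect_true(all(diff(areas) >= 0))
})

test_that("home-range areas are translation invariant", {
  set.seed(33)
  pts <- cbind(rnorm(200, 0, 25), rnorm(200, 0, 25))
  a1 <- kde_home_range(pts)$isopleths[["0.95"]]$area_ha
  a2 <- kde_home_range(pts + 5000)$isopleths[["0.95"]]$area_ha
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("hr_summary reports hectares and rejects degenerate input", {
  sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  expect_equal(polygon_area_ha(sq), 1)
  expect_error(polygon_area_ha(cbind(x = c(0, 1), y = c(0, 1))), "degenerate")
  expect_error(kde_home_range(cbind(1:20, 1:20)), "few points|degenerate")
  expect_error(kde_home_range(cbind(1:40, rep(2, 40))), "degenerate")
})

test_that("the generator's planted area is recovered by the KDE isopleth", {
  # synthetic scans emulate a group with a 10 ha range
  set.seed(34)
  hr_poly <- circle_poly(500, 500, sqrt(10 * 1e4 / pi))
  scans <- runif_in_polygon(1000, scale_polygon(hr_poly, 0.90))
  hr <- kde_home_range(scans, group_id = "T")
  tab <- hr_summary(hr)
  expect_lt(abs(tab$area_ha / 10 - 1), 0.2)
  expect_equal(tab$group_id, "T")
})
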