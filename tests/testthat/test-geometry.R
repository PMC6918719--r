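test_that("resample_path spaces vertices evenly and preserves length", {
  straight <- cbind(c(0, 100), c(0, 0))
  r <- resample_path(straight, 1)
  expect_equal(nrow(r), 101)
  expect_equal(path_length(r), 100)

  set.seed(11)
  for (i in 1:20) {
    p <- random_path(runif(1, 30, 150))
    r <- resample_path(p, 1)
    expect_equal(path_length(r), path_length(p), tolerance = 1e-6)
    gaps <- diff(attr(r, "s"))
    expect_true(all(gaps <= 1 + 1e-9))
  }

  # closed loop: endpoints preserved, length preserved, no extra duplication
  loop <- circle_poly(0, 0, 30, n = 40)
  loop <- rbind(loop, loop[1, ])
  r <- resample_path(loop, 1)
  expect_equal(path_length(r), path_length(loop), tolerance = 1e-6)
  expect_equal(unname(r[1, ]), unname(r[nrow(r), ]), tolerance = 1e-9)
  expect_error(resample_path(cbind(1, 2)), "fewer than 2")
})

test_that("dist_to_path agrees with a brute-force point/segment oracle", {
  set.seed(7)
  for (i in 1:25) {
    path <- random_path(60)
    pts <- cbind(runif(40, -50, 100), runif(40, -50, 100))
    got <- dist_to_path(pts, path)
    want <- apply(pts, 1, function(p) {
      mins <- sapply(seq_len(nrow(path) - 1), function(k) {
        a <- path[k, ]; b <- path[k + 1, ]
        ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
        t <- min(1, max(0, t))
        sqrt(sum((a + t * ab - p)^2))
      })
      min(mins)
    })
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("polygon predicates: containment, area, translation invariance", {
  sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  expect_equal(polygon_area(sq), 1e4)
  tri <- cbind(x = c(0, 4, 0), y = c(0, 0, 3))
  expect_equal(polygon_area(tri), 6)
  shifted <- cbind(tri[, 1] + 1234.5, tri[, 2] - 987)
  expect_equal(polygon_area(shifted), 6)

  pts <- cbind(c(50, 150, 0), c(50, 50, 100))
  inside <- point_in_polygon(pts, sq)
  expect_equal(inside[1:2], c(TRUE, FALSE))

  # ring + hole via even-odd parity
  hole <- cbind(x = c(40, 60, 60, 40), y = c(40, 40, 60, 60))
  expect_false(point_in_polygon(cbind(50, 50), list(sq, hole)))
  expect_true(point_in_polygon(cbind(20, 20), list(sq, hole)))
})

test_that("segment-rectangle intersection uses closed boundaries", {
  # crossing, corner touch, disjoint
  expect_true(segment_intersects_rect(-5, 5, 15, 5, 0, 10, 0, 10))
  expect_true(segment_intersects_rect(10, 10, 20, 10, 0, 10, 0, 10))   # corner
  expect_true(segment_intersects_rect(-5, -5, 10, 10, 0, 10, 0, 10))
  expect_false(segment_intersects_rect(11, 0, 20, 10, 0, 10, 0, 10))
  expect_false(segment_intersects_rect(-5, 11, 15, 11, 0, 10, 0, 10))
})

test_that("runif_in_polygon respects polygon and holes", {
  set.seed(5)
  poly <- circle_poly(0, 0, 50)
  hole <- circle_poly(0, 0, 20)
  p <- runif_in_polygon(300, poly, holes = list(hole))
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_true(all(r <= 50 + 1e-9))
  expect_true(all(r >= 20 - 1e-6))
  expect_error(runif_in_polygon(10, hole, holes = list(poly)), "empty")
})

test_that("path bearings are direction-agnostic", {
  p <- resample_path(cbind(c(0, 100), c(0, 50)), 1)
  q <- resample_path(cbind(c(100, 0), c(50, 0)), 1)
  bp <- path_bearings(p); bq <- path_bearings(q)
  expect_true(all(abs(bp - bq[length(bq):1]) < 1e-6 |
                  abs(abs(bp - bq[length(bq):1]) - 180) < 1e-6))
})
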