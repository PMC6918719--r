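test_that("a mixed model with no group variance reduces to OLS", {
  set.seed(21)
  n <- 400
  g <- rep(letters[1:4], each = n / 4)
  # covariates and noise centered within groups: the between-group variance
  # is exactly zero, so the ML variance estimate sits on the boundary
  ctr <- function(v) v - ave(v, g)
  dat <- data.frame(group_id = g, x1 = ctr(rnorm(n)), x2 = ctr(rnorm(n)))
  dat$y <- 1 + 0.5 * dat$x1 - 0.3 * dat$x2 + ctr(rnorm(n))
  spec <- model_spec("y", c("x1", "x2"), "group_id", "gaussian",
                     random_slopes = character(0))
  fit <- fit_mixed(spec, dat)
  ols <- coef(lm(y ~ x1 + x2, dat))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-4)
})

test_that("the observed-vs-simulated count model runs on a 32-row table", {
  set.seed(22)
  bc <- expand.grid(group_id = paste0("G", 1:4), buffer_m = c(5, 10, 15, 20))
  bc$observed_count <- 20 + 2 * bc$buffer_m + rnorm(16, 0, 3)
  bc$sim_mean <- 15 + 2 * bc$buffer_m + rnorm(16, 0, 3)
  m1dat <- rbind(
    data.frame(group_id = bc$group_id, buffer_m = bc$buffer_m,
               n_fts = bc$observed_count, loc_type = "observed"),
    data.frame(group_id = bc$group_id, buffer_m = bc$buffer_m,
               n_fts = bc$sim_mean, loc_type = "simulated"))
  spec <- model_spec("n_fts", c("loc_type", "buffer_m"), "group_id", "gaussian")
  fit <- fit_mixed(spec, m1dat)
  expect_equal(nrow(m1dat), 32)
  expect_true(is.finite(fit$loglik))
  expect_true(any(grepl("^loc_type", fit$coefficients$term)))
})

test_that("autocorrelation term matches hand computations and limits", {
  # constant residual field reproduces the constant
  set.seed(23)
  co <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  expect_equal(autocorr_term(rep(2.5, 8), co, rep(1, 8), D = 4), rep(2.5, 8))

  # two points: each sees only the other
  expect_equal(autocorr_term(c(1, -1), cbind(c(0, 10), c(0, 0)),
                             c(1, 1), D = 5), c(-1, 1))

  # D -> infinity: leave-one-out group mean
  r <- rnorm(6)
  got <- autocorr_term(r, co[1:6, ], rep(1, 6), D = 1e9)
  want <- vapply(1:6, function(i) mean(r[-i]), 0)
  expect_equal(got, want, tolerance = 1e-9)

  # groups are isolated; singletons get zero
  g <- c(1, 1, 1, 2, 2, 3)
  got <- autocorr_term(r, co[1:6, ], g, D = 10)
  expect_equal(got[6], 0)
  expect_equal(got[4], r[5])
  expect_equal(got[5], r[4])

  # rigid motion invariance
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(autocorr_term(r, co[1:6, ] %*% R + 100, rep(1, 6), 7),
               autocorr_term(r, co[1:6, ], rep(1, 6), 7), tolerance = 1e-9)

  expect_error(autocorr_term(r, co[1:6, ], g, D = 0), "D must be")
})

test_that("optimize_D returns the grid point maximising the likelihood", {
  set.seed(24)
  n <- 60
  dat <- data.frame(group_id = rep(c("a", "b"), each = n / 2),
                    x = runif(n, 0, 100), y = runif(n, 0, 100),
                    x1 = rnorm(n))
  dat$resp <- 0.4 * dat$x1 + rnorm(n)
  spec <- model_spec("resp", "x1", "group_id", "gaussian",
                     random_slopes = character(0))
  o <- optimize_D(spec, dat, D_grid = 7, random_slope_term = FALSE)
  expect_equal(o$D, 7)
  expect_equal(nrow(o$profile), 1)
  o2 <- optimize_D(spec, dat, D_grid = c(3, 9), random_slope_term = FALSE)
  expect_equal(o2$D, o2$profile$D[which.max(o2$profile$loglik)])
  expect_true(all(c("ac_term") %in% o2$fit$coefficients$term))
})

test_that("likelihood-ratio tests behave at the boundaries and under power", {
  set.seed(25)
  n <- 200
  dat <- data.frame(group_id = rep(letters[1:4], each = n / 4), x1 = rnorm(n))
  dat$y <- 2 + 1.5 * dat$x1 + rep(rnorm(4, 0, 0.3), each = n / 4) + rnorm(n)
  spec <- model_spec("y", "x1", "group_id", "gaussian",
                     random_slopes = character(0))
  full <- fit_mixed(spec, dat)
  same <- fit_mixed(spec, dat)
  eq <- lrt(full, same)
  expect_equal(eq$chi2, 0, tolerance = 1e-6)
  expect_equal(eq$p, 1)

  null <- fit_mixed(spec, dat, drop_terms = "x1")
  strong <- lrt(full, null)
  expect_lt(strong$p, 1e-10)
  expect_equal(strong$df, 1)
})

test_that("drop1 respects marginality and tests each droppable term once", {
  set.seed(26)
  n <- 600
  dat <- data.frame(group_id = rep(letters[1:3], each = n / 3),
                    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  dat$y <- 0.6 * dat$a - 0.4 * dat$a * dat$b + 0.0 * dat$c + rnorm(n)
  spec <- model_spec("y", c("a", "b", "c", "a:b"), "group_id", "gaussian",
                     random_slopes = character(0))
  d1 <- drop1_tests(spec, dat)
  expect_setequal(d1$term, c("a:b", "c"))   # a, b shielded by the interaction
  expect_lt(d1$p[d1$term == "a:b"], 0.01)
  expect_true(all(d1$df == 1))

  expect_error(model_spec("y", c("a", "a:b"), "group_id", "gaussian"),
               "main effect")
})

test_that("covariate standardization centers and scales", {
  d <- data.frame(u = c(1, 2, 3, 4), v = c(10, 10, 10, 10))
  s <- standardize_covariates(d, c("u", "v"))
  expect_equal(mean(s$u), 0)
  expect_equal(sd(s$u), 1)
  expect_equal(s$v, rep(0, 4))   # zero-variance column just centered
})

test_that("planted binomial effects are recovered with correct signs", {
  set.seed(27)
  n <- 800; g <- 4
  q <- data.frame(group_id = rep(paste0("g", 1:g), each = n),
                  ft_density = rnorm(n * g),
                  gap_presence = rbinom(n * g, 1, 0.3),
                  rel_elevation = rnorm(n * g))
  y <- simulate_route_presence(
    q, c("(Intercept)" = -0.5, ft_density = 0.9, gap_presence = -0.8,
         rel_elevation = 0.4, "rel_elevation:ft_density" = -0.45),
    group_effects = setNames(rnorm(g, 0, 0.3), paste0("g", 1:g)), seed = 28)
  q$presence <- as.integer(y)
  spec <- model_spec("presence",
                     c("ft_density", "gap_presence", "rel_elevation",
                       "rel_elevation:ft_density"),
                     "group_id", "binomial", random_slopes = character(0))
  fit <- fit_mixed(spec, q)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  inter <- grep("ft_density:|:ft_density", names(est), value = TRUE)
  expect_gt(est[["ft_density"]], 0)
  expect_lt(est[["gap_presence"]], 0)
  expect_length(inter, 1)
  expect_lt(est[[inter]], 0)
})
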