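test_that("the penalized objective matches hand-evaluated cases", {
  expect_equal(objective_g(50, 6.0, 500), 50)
  # 50 - 0.2 (12 - 6.57) - 1.8 (12 - 10)
  expect_equal(objective_g(50, 12, 500), 45.314)
  # 50 - 1.0 (400 - 300)
  expect_equal(objective_g(50, 6.0, 300), -50)
  # 50 - 0.1 (650 - 600)
  expect_equal(objective_g(50, 5, 650), 45)
})

test_that("the objective equals yield on the target region and is monotone in kappa", {
  set.seed(4)
  Y <- runif(50, 40, 60)
  K <- runif(50, 0, 6.57)
  eta <- runif(50, 400, 600)
  expect_equal(objective_g(Y, K, eta), Y)

  # piecewise-linear, continuous, non-increasing in kappa
  ks <- seq(0, 20, by = 0.01)
  g <- objective_g(50, ks, 500)
  expect_true(all(diff(g) <= 1e-12))
  # slope changes at the kinks are bounded by the summed weights, so the
  # second differences stay O(step): the function is continuous
  expect_lt(max(abs(diff(g, differences = 2))), 2.1 * 0.01)
})

test_that("feasibility excludes exactly the low-severity corner simplex", {
  expect_false(feasible(c(120, 60, 5)))
  expect_true(feasible(c(140, 60, 5)))   # boundary counts as feasible
  expect_true(feasible(c(160, 180, 10)))
  expect_true(feasible(c(120, 120, 5)))  # (0 + 1 + 0) on the boundary

  # convexity: midpoints of feasible pairs stay feasible
  set.seed(9)
  r <- pilot_ranges()
  U <- matrix(runif(300), ncol = 3)
  X <- to_natural(2 * U - 1, r)
  ok <- feasible(X, r)
  A <- X[ok, ][1:20, ]; B <- X[ok, ][21:40, ]
  expect_true(all(feasible((A + B) / 2, r)))
})

test_that("the excluded volume fraction is 1/48 analytically and by Monte Carlo", {
  expect_equal(excluded_volume_fraction(pilot_ranges()), 1 / 48,
               tolerance = 1e-12)
  expect_equal(excluded_volume_fraction(pilot_ranges(), threshold = 0), 0)
  expect_equal(excluded_volume_fraction(pilot_ranges(), threshold = -1), 0)
  # a threshold beyond the whole box excludes everything
  expect_equal(excluded_volume_fraction(pilot_ranges(), threshold = 7), 1)

  set.seed(1)
  n <- 2e5
  r <- pilot_ranges()
  X <- cbind(runif(n, 120, 160), runif(n, 60, 180), runif(n, 5, 10))
  frac <- mean(!feasible(X, r))
  se <- sqrt(frac * (1 - frac) / n)
  expect_lt(abs(frac - 1 / 48), 3 * se)
})

test_that("noisy EI collapses to classic expected improvement without noise", {
  set.seed(31)
  X <- matrix(runif(21), 7, 3)
  y <- 3 * X[, 1] - X[, 2]^2
  b <- rbind(rep(0, 3), rep(1, 3))
  m <- gp_model(X, y, lengthscale = 0.4, noise_var = 0, bounds = b)
  xs <- matrix(runif(30), 10, 3)
  nei <- noisy_ei(m, xs, n_mc = 4, seed = 1)
  nei2 <- noisy_ei(m, xs, n_mc = 512, seed = 2)
  # n_mc is irrelevant in the noiseless limit
  expect_equal(nei, nei2, tolerance = 1e-12)

  # closed-form EI oracle against the observed maximum
  p <- gp_posterior(m, xs)
  best <- max(y)
  z <- (p$mean - best) / sqrt(p$var)
  ei <- (p$mean - best) * pnorm(z) + sqrt(p$var) * dnorm(z)
  expect_equal(nei, ei, tolerance = 1e-6)
  expect_true(all(nei >= 0))
})

test_that("expected improvement at the incumbent mean with unit sd is phi(0)", {
  expect_equal(rsmbo:::ei_closed_form(5, 1, 5), dnorm(0), tolerance = 1e-12)
  expect_equal(rsmbo:::ei_closed_form(6, 0, 5), 1)   # deterministic gain
  expect_equal(rsmbo:::ei_closed_form(4, 0, 5), 0)
})

test_that("Monte-Carlo error of noisy EI shrinks like 1/sqrt(n_mc)", {
  set.seed(77)
  X <- matrix(runif(24), 8, 3)
  y <- X[, 1] + rnorm(8, 0, 0.3)
  b <- rbind(rep(0, 3), rep(1, 3))
  m <- gp_model(X, y, lengthscale = 0.4, noise_var = 0.2, bounds = b)
  x0 <- matrix(c(0.5, 0.5, 0.5), 1)
  est <- function(n_mc) vapply(1:24, function(s)
    noisy_ei(m, x0, n_mc = n_mc, seed = s), numeric(1))
  sd_small <- sd(est(8))
  sd_large <- sd(est(128))
  ratio <- sd_small / sd_large  # expect about sqrt(16) = 4
  expect_gt(ratio, 1.8)
})

test_that("proposals honor the feasibility constraint and the final-step argmax", {
  set.seed(15)
  r <- pilot_ranges()
  U <- matrix(runif(36), 12, 3)
  X <- to_natural(2 * U - 1, r)
  X <- X[feasible(X, r), , drop = FALSE]
  g <- objective_g(55 - 0.01 * (X[, 1] - 140)^2, 6, 500)
  m <- fit_gp_map(X, g, bounds = r, restarts = 4, seed = 3)

  for (s in c(1, 2)) {
    prop <- propose_next(m, r, constraint = TRUE, final = FALSE,
                         config = bo_config(n_screen = 512, n_polish = 3),
                         seed = s)
    expect_true(feasible(prop$x, r))
    expect_gte(prop$acq, 0)
  }

  propf <- propose_next(m, r, constraint = TRUE, final = TRUE,
                        config = bo_config(n_screen = 512, n_polish = 3),
                        seed = 4)
  expect_true(feasible(propf$x, r))
  # the returned value is the posterior mean there, and at least as large
  # as at independently sampled feasible points
  expect_equal(gp_posterior(m, matrix(propf$x, 1))$mean, propf$acq,
               tolerance = 1e-9)
  set.seed(99)
  probe <- to_natural(2 * matrix(runif(300), ncol = 3) - 1, r)
  probe <- probe[feasible(probe, r), , drop = FALSE]
  expect_gte(propf$acq, max(gp_posterior(m, probe)$mean) - 1e-6)
})

test_that("the loop finds the peak of a gentle noise-free surface", {
  r <- pilot_ranges()
  oracle <- gentle_peak(r, peak = c(135, 150, 8), height = 10)
  init <- rsmbo:::new_design_matrix(
    rbind(c(-1, -1, -1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1),
          c(0, 0, 0)), r)
  trace <- run_bo(oracle, init, n_adaptive = 10, weights = NULL,
                  ranges = r, constraint = FALSE,
                  config = bo_config(n_screen = 1024, n_polish = 4,
                                     restarts = 4), seed = 6)
  expect_equal(nrow(trace), 15)
  expect_true(all(diff(trace$best_so_far) >= 0))
  expect_lt(10 - max(trace$objective), 0.2)
  # the final (posterior-mean) proposal lies in the peak's basin
  final <- as.numeric(trace[15, r$name])
  expect_gt(oracle(matrix(final, 1))$yield, 9.5)
})

test_that("infeasible initialization is rejected when the constraint is on", {
  r <- pilot_ranges()
  bad <- rsmbo:::new_design_matrix(rbind(c(-1, -1, -1), c(0, 0, 0)), r)
  expect_error(run_bo(gentle_peak(r), bad, n_adaptive = 1,
                      weights = objective_weights(), ranges = r,
                      constraint = TRUE),
               "feasibility")
})
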