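test_that("Matern-5/2 kernel matches its closed form and is monotone", {
  expect_equal(matern52(0, 1, 2.5), 2.5)
  # direct evaluation of sigma2 (1 + sqrt5 r + 5 r^2 / 3) exp(-sqrt5 r)
  r <- 1
  expect_equal(matern52(1),
               (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r))
  expect_equal(matern52(1), 0.5240, tolerance = 1e-3)
  v <- matern52(seq(0.01, 5, by = 0.01))
  expect_true(all(diff(v) < 0))
  expect_error(matern52(1, lengthscale = -1), "positive")
  expect_error(matern52(-0.5), "nonnegative")
})

test_that("posterior mean and variance agree with a dense linear-algebra oracle", {
  set.seed(14)
  X <- matrix(runif(24), 8, 3)
  y <- sin(3 * X[, 1]) + X[, 2]^2 - 0.5 * X[, 3]
  ell <- c(0.4, 0.6, 0.8); sf2 <- 1.3; sn2 <- 0.05
  b <- rbind(rep(0, 3), rep(1, 3))
  m <- gp_model(X, y, lengthscale = ell, signal_var = sf2, noise_var = sn2,
                bounds = b, standardize = FALSE)
  Xnew <- matrix(runif(15), 5, 3)

  # oracle: kernel and solve written independently
  kmat <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      r <- sqrt(sum(((A[i, ] - B[j, ]) / ell)^2))
      K[i, j] <- sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
    }
    K
  }
  K <- kmat(X, X) + diag(sn2, 8)
  Ks <- kmat(Xnew, X)
  mu_oracle <- Ks %*% solve(K, y)
  var_oracle <- sf2 - diag(Ks %*% solve(K, t(Ks)))

  p <- gp_posterior(m, Xnew)
  expect_equal(p$mean, drop(mu_oracle), tolerance = 1e-8)
  expect_equal(p$var, var_oracle, tolerance = 1e-8)
})

test_that("noise-free GP interpolates and reverts to the prior far away", {
  set.seed(3)
  X <- matrix(runif(18), 6, 3)
  y <- 2 + X[, 1] - X[, 2]
  m <- gp_model(X, y, lengthscale = 0.3, noise_var = 0,
                bounds = rbind(rep(0, 3), rep(1, 3)))
  p <- gp_posterior(m, X)
  expect_equal(p$mean, y, tolerance = 1e-4)
  expect_true(all(p$var < 1e-4 * var(y)))

  far <- matrix(rep(50, 3), 1)
  pf <- gp_posterior(m, far)
  expect_equal(pf$mean, mean(y), tolerance = 1e-6)
  expect_equal(pf$var, m$signal_var * m$y_sd^2, tolerance = 1e-6)
})

test_that("MAP estimation recovers a known length scale from simulated data", {
  set.seed(21)
  n <- 60
  X <- matrix(sort(runif(n)), ncol = 1)
  ell_true <- 0.2
  D <- outer(drop(X), drop(X), "-")
  r <- abs(D) / ell_true
  K <- (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  y <- drop(t(chol(K + diag(1e-10, n))) %*% rnorm(n))
  m <- fit_gp_map(X, y, bounds = rbind(0, 1), restarts = 6, seed = 2,
                  fixed_noise = 1e-8)
  expect_lt(abs(log(m$lengthscale) - log(ell_true)), 0.5)
})

test_that("duplicated inputs with conflicting responses force positive noise", {
  X <- matrix(c(0.2, 0.2, 0.8, 0.5,
                0.2, 0.2, 0.3, 0.9), ncol = 2)
  y <- c(1, 3, 0.5, 2)
  m <- fit_gp_map(X, y, bounds = rbind(c(0, 0), c(1, 1)), seed = 1)
  expect_gt(m$noise_var, 1e-3)
})

test_that("the MAP optimum beats the prior-mode start point", {
  set.seed(6)
  X <- matrix(runif(30), 10, 3)
  y <- X[, 1] * 2 + rnorm(10, 0, 0.1)
  m <- fit_gp_map(X, y, bounds = rbind(rep(0, 3), rep(1, 3)), seed = 4)
  ys <- (y - m$y_mean) / m$y_sd
  D2 <- rsmbo:::dim_sqdiff(m$U, m$U)
  start <- c(rep(log(0.5), 3), 0, log(0.05))
  at_mode <- -rsmbo:::gp_neg_log_post(start, D2, ys, gp_priors())
  expect_gte(m$map_objective, at_mode)
})

test_that("fits are equivariant under shifting and scaling the response", {
  set.seed(8)
  X <- matrix(runif(27), 9, 3)
  y <- sin(4 * X[, 1]) + X[, 3]
  b <- rbind(rep(0, 3), rep(1, 3))
  m1 <- fit_gp_map(X, y, bounds = b, seed = 5)
  m2 <- fit_gp_map(X, 10 * y + 100, bounds = b, seed = 5)
  Xn <- matrix(runif(9), 3, 3)
  p1 <- gp_posterior(m1, Xn); p2 <- gp_posterior(m2, Xn)
  expect_equal(p2$mean, 10 * p1$mean + 100, tolerance = 1e-6)
  expect_equal(p2$var, 100 * p1$var, tolerance = 1e-5)
})

test_that("adding an observation cannot increase noise-free posterior variance", {
  set.seed(12)
  X <- matrix(runif(15), 5, 3)
  y <- X[, 1] + X[, 2]
  b <- rbind(rep(0, 3), rep(1, 3))
  m1 <- gp_model(X, y, lengthscale = 0.5, noise_var = 0, bounds = b)
  xnew <- matrix(c(0.42, 0.17, 0.66), 1)
  X2 <- rbind(X, c(0.3, 0.9, 0.1))
  m2 <- gp_model(X2, c(y, 1.2), lengthscale = 0.5, noise_var = 0,
                 bounds = b, standardize = FALSE)
  m1b <- gp_model(X, y, lengthscale = 0.5, noise_var = 0, bounds = b,
                  standardize = FALSE)
  expect_lte(gp_posterior(m2, xnew)$var,
             gp_posterior(m1b, xnew)$var + 1e-8)
})

test_that("a GP model serializes its hyperparameters to JSON", {
  set.seed(2)
  X <- matrix(runif(12), 4, 3)
  m <- gp_model(X, rnorm(4), lengthscale = 0.5)
  path <- tempfile(fileext = ".json")
  gp_to_json(m, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$kernel, "matern52")
  expect_equal(unlist(js$lengthscale), unname(m$lengthscale))
  expect_equal(js$n, 4)
  unlink(path)
})
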