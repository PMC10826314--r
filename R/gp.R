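#' Matern-5/2 covariance function
#'
#' `variance * (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) * exp(-sqrt(5) r / l)`.
#' With anisotropic (per-dimension) length scales, `r` is the scaled
#' Euclidean distance and `l = 1`.
#'
#' @param r nonnegative distance(s).
#' @param lengthscale positive length scale.
#' @param variance positive signal variance.
#' @return Covariance value(s).
#' @examples
#' matern52(0)          # equals the signal variance
#' matern52(1)          # ~ 0.524
#' @export
matern52 <- function(r, lengthscale = 1, variance = 1) {
  if (any(lengthscale <= 0) || any(variance <= 0))
    stop("lengthscale and variance must be positive")
  if (any(r < 0)) stop("distances must be nonnegative")
  z <- sqrt(5) * r / lengthscale
  variance * (1 + z + z^2 / 3) * exp(-z)
}

#' Hyperparameter priors for GP regression
#'
#' Gamma priors on the anisotropic length scales (of inputs normalized to
#' the unit cube) and on the noise variance (of outputs standardized to
#' unit variance); the signal variance gets a flat prior on the log scale.
#' The default length-scale prior, Gamma(3, 6) (mean 0.5 in unit-cube
#' units), mirrors widely used Bayesian-optimization practice. The noise
#' prior Gamma(1.5, 15) (mode 0.033 of the output variance) is weakly
#' informative: with a dozen or so observations the marginal likelihood
#' barely identifies the noise variance and a nearly flat prior lets the
#' estimate collapse to interpolation of the measurement noise, while
#' truly noise-free data still overwhelm this prior and drive the
#' estimate toward zero.
#'
#' @param lengthscale,noise numeric `c(shape, rate)` pairs.
#' @return A list of class `gp_priors`.
#' @export
gp_priors <- function(lengthscale = c(shape = 3, rate = 6),
                      noise = c(shape = 1.5, rate = 15)) {
  stopifnot(all(lengthscale > 0), all(noise > 0))
  structure(list(lengthscale = lengthscale, noise = noise),
            class = "gp_priors")
}

## squared differences per input dimension, list of n x m matrices
dim_sqdiff <- function(A, B) {
  lapply(seq_len(ncol(A)), function(k) outer(A[, k], B[, k], "-")^2)
}

## Matern-5/2 ARD kernel from per-dimension squared differences
ard_kernel <- function(D2, ell, sf2) {
  r2 <- Reduce(`+`, Map(function(d2, l) d2 / l^2, D2, as.list(ell)))
  r <- sqrt(pmax(r2, 0))
  z <- sqrt(5) * r
  sf2 * (1 + z + z^2 / 3) * exp(-z)
}

chol_jitter <- function(K) {
  for (j in c(0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6)) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is not positive definite even with jitter 1e-6")
}

normalize_inputs <- function(X, bounds) {
  if (inherits(bounds, "factor_ranges")) {
    lo <- bounds$low; span <- bounds$high - bounds$low
  } else if (is.null(bounds)) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    span <- ifelse(hi > lo, hi - lo, 1)
  } else {
    lo <- bounds[1, ]; span <- bounds[2, ] - bounds[1, ]
  }
  list(lo = lo, span = span,
       U = sweep(sweep(X, 2, lo, "-"), 2, span, "/"))
}

## negative log posterior and gradient; theta = (log ell_1..d, log sf2
## [, log sn2]); y standardized. D2 precomputed on normalized inputs.
gp_neg_log_post <- function(theta, D2, y, priors, fixed_noise = NULL,
                            grad = FALSE) {
  d <- length(D2)
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1])
  sn2 <- if (is.null(fixed_noise)) exp(theta[d + 2]) else fixed_noise
  n <- length(y)
  Kf <- ard_kernel(D2, ell, sf2)
  K <- Kf + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(L)) return(if (grad) NULL else 1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  pl <- priors$lengthscale
  lp <- sum((pl[1] - 1) * log(ell) - pl[2] * ell)
  if (is.null(fixed_noise)) {
    pn <- priors$noise
    lp <- lp + (pn[1] - 1) * log(sn2) - pn[2] * sn2
  }
  if (!grad) return(nll - lp)
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha)    # 0.5 tr(W dK) is d(nll)
  r2 <- Reduce(`+`, Map(function(d2, l) d2 / l^2, D2, as.list(ell)))
  r <- sqrt(pmax(r2, 0))
  E <- exp(-sqrt(5) * r)
  G <- sf2 * (5 / 3) * (1 + sqrt(5) * r) * E
  g <- numeric(length(theta))
  for (k in seq_len(d)) {
    dK <- G * (D2[[k]] / ell[k]^2)
    g[k] <- 0.5 * sum(W * dK) - ((pl[1] - 1) - pl[2] * ell[k])
  }
  g[d + 1] <- 0.5 * sum(W * Kf)
  if (is.null(fixed_noise)) {
    pn <- priors$noise
    g[d + 2] <- 0.5 * sum(diag(W)) * sn2 - ((pn[1] - 1) - pn[2] * sn2)
  }
  g
}

#' Fit a Gaussian process by maximum a posteriori estimation
#'
#' Gaussian-process regression with a Matern-5/2 kernel, anisotropic
#' length scales, and homoscedastic Gaussian noise. Inputs are normalized
#' to the unit cube and outputs standardized before fitting; length
#' scales, signal variance, and noise variance are chosen by maximizing
#' the log marginal likelihood plus log prior with multi-start local
#' optimization (L-BFGS-B with analytic gradients).
#'
#' @param X numeric matrix of inputs (rows = observations).
#' @param y numeric response vector.
#' @param bounds a [factor_ranges()] (or `rbind(low, high)` matrix) used
#'   to normalize inputs; defaults to the data range.
#' @param priors a [gp_priors()] object.
#' @param restarts number of optimizer starts (default 8, quasi-random).
#' @param seed integer seed making the starts reproducible.
#' @param fixed_noise optionally pin the noise variance (standardized
#'   output scale), e.g. 0 for noise-free interpolation.
#' @return An object of class `gp_model`: hyperparameters (`lengthscale`,
#'   `signal_var`, `noise_var`, on normalized scales), normalization
#'   constants, training data, and the MAP objective value.
#' @export
fit_gp_map <- function(X, y, bounds = NULL, priors = gp_priors(),
                       restarts = 8, seed = 1, fixed_noise = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("inputs and responses must be finite")
  if (nrow(unique(X)) < 2) stop("need at least 2 distinct inputs")
  stopifnot(nrow(X) == length(y))
  nz <- normalize_inputs(X, bounds)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  D2 <- dim_sqdiff(nz$U, nz$U)
  d <- ncol(X)
  np <- d + 1 + is.null(fixed_noise)
  ## quasi-random starts around the priors, plus one default start
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  S <- lhs::randomLHS(max(restarts - 1, 1), np)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  lo <- c(rep(log(0.05), d), log(0.1), if (is.null(fixed_noise)) log(1e-6))
  hi <- c(rep(log(2), d), log(10), if (is.null(fixed_noise)) log(0.5))
  starts <- rbind(c(rep(log(0.5), d), 0, if (is.null(fixed_noise)) log(0.05)),
                  sweep(sweep(S, 2, hi - lo, "*"), 2, lo, "+"))
  starts <- starts[seq_len(max(restarts, 1)), , drop = FALSE]
  lower <- c(rep(log(1e-3), d), -10, if (is.null(fixed_noise)) log(1e-8))
  upper <- c(rep(log(1e3), d), 10, if (is.null(fixed_noise)) log(10))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ],
                   fn = function(th)
                     gp_neg_log_post(th, D2, ys, priors, fixed_noise),
                   gr = function(th)
                     gp_neg_log_post(th, D2, ys, priors, fixed_noise,
                                     grad = TRUE),
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("GP hyperparameter optimization failed at every start point")
  th <- best$par
  ell <- exp(th[seq_len(d)])
  sf2 <- exp(th[d + 1])
  sn2 <- if (is.null(fixed_noise)) exp(th[d + 2]) else fixed_noise
  Kf <- ard_kernel(D2, ell, sf2)
  L <- chol_jitter(Kf + diag(sn2 + 1e-10, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(lengthscale = ell, signal_var = sf2, noise_var = sn2,
                 x_lo = nz$lo, x_span = nz$span,
                 y_mean = y_mean, y_sd = y_sd,
                 U = nz$U, ys = ys, X = X, y = y,
                 L = L, alpha = alpha,
                 map_objective = -best$value, priors = priors,
                 fixed_noise = fixed_noise),
            class = "gp_model")
}

#' Construct a GP model with given hyperparameters
#'
#' Builds a `gp_model` directly from supplied hyperparameters without MAP
#' estimation (useful for controlled analyses and tests).
#'
#' @inheritParams fit_gp_map
#' @param lengthscale,signal_var,noise_var hyperparameters on the
#'   normalized input / standardized output scales.
#' @param standardize standardize `y` (default TRUE).
#' @return A `gp_model`.
#' @export
gp_model <- function(X, y, lengthscale, signal_var = 1, noise_var = 0,
                     bounds = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  nz <- normalize_inputs(X, bounds)
  y_mean <- if (standardize) mean(y) else 0
  y_sd <- if (standardize) stats::sd(y) else 1
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  if (length(lengthscale) == 1) lengthscale <- rep(lengthscale, ncol(X))
  Kf <- ard_kernel(dim_sqdiff(nz$U, nz$U), lengthscale, signal_var)
  L <- chol_jitter(Kf + diag(noise_var + 1e-10, nrow(X)))
  structure(list(lengthscale = lengthscale, signal_var = signal_var,
                 noise_var = noise_var, x_lo = nz$lo, x_span = nz$span,
                 y_mean = y_mean, y_sd = y_sd, U = nz$U, ys = ys,
                 X = X, y = y, L = L,
                 alpha = backsolve(L, forwardsolve(t(L), ys)),
                 map_objective = NA_real_, priors = NULL,
                 fixed_noise = noise_var), class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("Matern-5/2 GP on", nrow(x$X), "observations\n")
  cat("  length scales:", signif(x$lengthscale, 4), "\n")
  cat(sprintf("  signal var %.4g, noise var %.4g (standardized scale)\n",
              x$signal_var, x$noise_var))
  invisible(x)
}

gp_normalize_new <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(model$X)) Xnew <- matrix(Xnew, ncol = ncol(model$X))
  sweep(sweep(Xnew, 2, model$x_lo, "-"), 2, model$x_span, "/")
}

#' GP posterior mean and variance
#'
#' Standard Gaussian-process conditional mean and variance at new points,
#' de-standardized to original response units. By default the variance is
#' that of the latent function (excluding observation noise); set
#' `include_noise = TRUE` for the predictive variance of a new noisy
#' observation.
#'
#' @param model a `gp_model`.
#' @param Xnew matrix of new input points (original units).
#' @param include_noise add the observation-noise variance.
#' @return A list with `mean` and `var` vectors in original units.
#' @export
gp_posterior <- function(model, Xnew, include_noise = FALSE) {
  Un <- gp_normalize_new(model, Xnew)
  Ks <- ard_kernel(dim_sqdiff(Un, model$U), model$lengthscale,
                   model$signal_var)
  mu <- drop(Ks %*% model$alpha)
  v <- forwardsolve(t(model$L), t(Ks))
  var_s <- pmax(model$signal_var - colSums(v^2), 0)
  if (include_noise) var_s <- var_s + model$noise_var
  list(mean = mu * model$y_sd + model$y_mean,
       var = var_s * model$y_sd^2)
}

## joint posterior of the latent function at Xnew: mean vector and
## covariance matrix in original units (used for sampling g_max in NEI)
gp_joint_posterior <- function(model, Xnew) {
  Un <- gp_normalize_new(model, Xnew)
  Ks <- ard_kernel(dim_sqdiff(Un, model$U), model$lengthscale,
                   model$signal_var)
  Kss <- ard_kernel(dim_sqdiff(Un, Un), model$lengthscale,
                    model$signal_var)
  mu <- drop(Ks %*% model$alpha)
  v <- forwardsolve(t(model$L), t(Ks))
  S <- Kss - crossprod(v)
  S <- (S + t(S)) / 2
  list(mean = mu * model$y_sd + model$y_mean, cov = S * model$y_sd^2)
}

#' Serialize a GP model to JSON
#'
#' Writes hyperparameters, normalization constants and a training-data
#' checksum; enough to audit or re-create the fit from the training CSV.
#'
#' @param model a `gp_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
gp_to_json <- function(model, path) {
  chk <- sum(model$X) + sum(model$y) + nrow(model$X) * 1e-6
  jsonlite::write_json(list(
    kernel = "matern52",
    lengthscale = model$lengthscale,
    signal_var = model$signal_var,
    noise_var = model$noise_var,
    x_lo = model$x_lo, x_span = model$x_span,
    y_mean = model$y_mean, y_sd = model$y_sd,
    n = nrow(model$X), training_checksum = chk),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
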