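#' Penalty weights and response targets for the delignification objective
#'
#' The scalar objective rewards cellulose yield and penalizes kappa
#' number above its target (softly above 6.57, heavily above 10) and pulp
#' viscosity outside the dissolving-pulp window 400--600 mL/g.
#'
#' @param w1,w2,w3,w4 nonnegative penalty weights (defaults 0.2, 1.8,
#'   1.0, 0.1).
#' @param kappa_soft,kappa_hard kappa thresholds (6.57, 10).
#' @param visc_low,visc_high viscosity window in mL/g (400, 600).
#' @return A list of class `objective_weights`.
#' @export
objective_weights <- function(w1 = 0.2, w2 = 1.8, w3 = 1.0, w4 = 0.1,
                              kappa_soft = 6.57, kappa_hard = 10,
                              visc_low = 400, visc_high = 600) {
  w <- c(w1, w2, w3, w4)
  if (any(w < 0)) stop("penalty weights must be nonnegative (w",
                       which(w < 0)[1], " is negative)")
  if (visc_low >= visc_high)
    stop("visc_low must be below visc_high")
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4,
                 kappa_soft = kappa_soft, kappa_hard = kappa_hard,
                 visc_low = visc_low, visc_high = visc_high),
            class = "objective_weights")
}

#' Penalized scalar objective for pulp quality
#'
#' `g(Y, K, eta) = Y - w1 max(0, K - 6.57) - w2 max(0, K - 10)
#'  - w3 max(0, 400 - eta) - w4 max(0, eta - 600)`.
#' Equals the cellulose yield `Y` whenever kappa and viscosity are inside
#' their target ranges; piecewise linear and continuous in `K` and `eta`.
#'
#' @param yield cellulose yield, percent.
#' @param kappa kappa number.
#' @param viscosity pulp viscosity, mL/g.
#' @param w an [objective_weights()] object.
#' @return The objective value(s).
#' @examples
#' objective_g(50, 6.0, 500)   # 50: inside all targets
#' objective_g(50, 12, 500)    # penalized kappa
#' @export
objective_g <- function(yield, kappa, viscosity, w = objective_weights()) {
  yield - w$w1 * pmax(0, kappa - w$kappa_soft) -
    w$w2 * pmax(0, kappa - w$kappa_hard) -
    w$w3 * pmax(0, w$visc_low - viscosity) -
    w$w4 * pmax(0, viscosity - w$visc_high)
}

#' Feasibility constraint excluding the low-severity corner
#'
#' The corner of the search box where all factors are near their minima
#' is ruled out a priori: a point is feasible iff the scaled sum
#' `sum_i (x_i - low_i) / half_range_i >= threshold`, with
#' `half_range_i = (high_i - low_i) / 2`. For the delignification box
#' this is `(T-120)/20 + (tau-60)/60 + (R-5)/2.5 >= 1`, and the boundary
#' counts as feasible. The excluded region is a corner simplex, so the
#' feasible region is convex.
#'
#' @param x point(s) in natural units (vector, matrix or data.frame).
#' @param ranges [factor_ranges()] of the search box.
#' @param threshold constraint threshold (default 1).
#' @return Logical vector.
#' @examples
#' feasible(c(120, 60, 5))   # FALSE: the excluded corner
#' feasible(c(140, 60, 5))   # TRUE: exactly on the boundary
#' @export
feasible <- function(x, ranges = pilot_ranges(), threshold = 1) {
  x <- as_point_matrix(x, ranges)
  s <- sweep(sweep(x, 2, ranges$low, "-"), 2, range_half(ranges), "/")
  rowSums(s) >= threshold - 1e-12
}

#' Volume fraction excluded by the corner constraint
#'
#' Analytic fraction of the box volume violating the feasibility
#' constraint of [feasible()]: the excluded set `{sum_i 2 u_i < t}` over
#' the unit cube has volume `sum_S (-1)^|S| (t - 2|S|)_+^d / (d! 2^d)`
#' by inclusion-exclusion.
#'
#' @inheritParams feasible
#' @return The excluded volume fraction in `[0, 1]`; `1/48` for the
#'   default box and threshold.
#' @export
excluded_volume_fraction <- function(ranges = pilot_ranges(), threshold = 1) {
  d <- nrow(ranges)
  a <- rep(2, d)  # unit-cube scaling of (x - low) / half_range
  total <- 0
  for (m in 0:d) {
    if (m == 0) {
      total <- total + max(threshold, 0)^d
    } else {
      cm <- utils::combn(d, m)
      for (j in seq_len(ncol(cm))) {
        s <- sum(a[cm[, j]])
        total <- total + (-1)^m * max(threshold - s, 0)^d
      }
    }
  }
  min(max(total / (factorial(d) * prod(a)), 0), 1)
}

## closed-form expected improvement of N(mu, sd^2) over incumbent `best`
ei_closed_form <- function(mu, sd, best) {
  out <- pmax(mu - best, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- (mu[pos] - best) / sd[pos]
    out[pos] <- (mu[pos] - best) * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  out
}

## Monte-Carlo draws of the incumbent g_max: joint posterior samples of
## the latent objective at the training conditions, maximized per sample.
## With (near-)zero observation noise the posterior at the training data
## is degenerate and g_max collapses to the observed maximum.
draw_gmax <- function(model, n_mc, seed) {
  post <- gp_posterior(model, model$X)
  if (model$noise_var <= 1e-9) return(max(post$mean))
  jp <- gp_joint_posterior(model, model$X)
  L <- chol_jitter(jp$cov + diag(1e-12 * max(diag(jp$cov), 1),
                                 nrow(jp$cov)))
  Z <- with_seed(seed, matrix(stats::rnorm(n_mc * length(jp$mean)),
                              nrow = n_mc))
  samples <- sweep(Z %*% L, 2, jp$mean, "+")
  apply(samples, 1, max)
}

## acquisition over rows of Xnew given fixed g_max draws (vectorized
## over both candidate points and incumbent samples)
nei_given_gmax <- function(model, Xnew, gmax) {
  post <- gp_posterior(model, Xnew)
  mu <- post$mean
  sd <- sqrt(pmax(post$var, 0))
  if (length(gmax) == 1) return(ei_closed_form(mu, sd, gmax))
  D <- outer(mu, gmax, "-")
  out <- numeric(length(mu))
  pos <- sd > 0
  if (any(pos)) {
    Dp <- D[pos, , drop = FALSE]
    Z <- Dp / sd[pos]
    out[pos] <- rowMeans(Dp * stats::pnorm(Z) + sd[pos] * stats::dnorm(Z))
  }
  if (any(!pos)) out[!pos] <- rowMeans(pmax(D[!pos, , drop = FALSE], 0))
  out
}

#' Noisy expected improvement acquisition
#'
#' Monte-Carlo estimate of the expected improvement over the (uncertain)
#' best objective value reached so far: joint posterior samples of the
#' latent objective at all previous experiment conditions define a sample
#' of incumbents `g_max`; the acquisition averages the closed-form
#' expected improvement at `x` against each sampled incumbent. With zero
#' observation noise the incumbent distribution collapses to the observed
#' maximum and the classic expected improvement is returned exactly.
#'
#' @param model a fitted `gp_model` on objective values.
#' @param x candidate point(s), natural units.
#' @param n_mc number of Monte-Carlo incumbent draws (default 128).
#' @param seed integer seed for the draws.
#' @return Nonnegative acquisition value(s), deterministic given seed.
#' @export
noisy_ei <- function(model, x, n_mc = 128, seed = 1) {
  gmax <- draw_gmax(model, n_mc, seed)
  nei_given_gmax(model, as_gp_input(model, x), gmax)
}

as_gp_input <- function(model, x) {
  if (is.null(dim(x))) matrix(x, ncol = ncol(model$X)) else as.matrix(x)
}

#' Acquisition and loop settings for Bayesian optimization
#'
#' @param n_screen size of the quasi-random feasibility-filtered screen
#'   used to seed acquisition maximization.
#' @param n_polish number of top screen points polished by local search.
#' @param n_mc Monte-Carlo incumbent draws for noisy expected improvement.
#' @param restarts GP hyperparameter optimizer restarts per refit.
#' @param priors [gp_priors()] for the GP refits.
#' @return A list of class `bo_config`.
#' @export
bo_config <- function(n_screen = 4096, n_polish = 10, n_mc = 128,
                      restarts = 8, priors = gp_priors()) {
  structure(list(n_screen = n_screen, n_polish = n_polish, n_mc = n_mc,
                 restarts = restarts, priors = priors),
            class = "bo_config")
}

#' Propose the next experiment
#'
#' For all but the final iteration, returns an approximate feasible
#' maximizer of the noisy-expected-improvement acquisition; on the final
#' iteration, of the posterior mean (pure exploitation). Maximization
#' screens a quasi-random set of feasible points and polishes the best
#' ones with local search; the returned point always satisfies the
#' feasibility constraint when it is switched on.
#'
#' @param model a fitted `gp_model` on objective values.
#' @param ranges [factor_ranges()] search box.
#' @param constraint apply the corner-exclusion constraint of
#'   [feasible()].
#' @param final maximize the posterior mean instead of the acquisition.
#' @param config a [bo_config()].
#' @param seed integer seed (screen + incumbent draws).
#' @return A list with `x` (named natural-unit conditions) and `acq`
#'   (acquisition or posterior-mean value at the proposal).
#' @export
propose_next <- function(model, ranges, constraint = TRUE, final = FALSE,
                         config = bo_config(), seed = 1) {
  d <- nrow(ranges)
  U <- with_seed(seed, lhs::randomLHS(config$n_screen, d))
  Xs <- sweep(sweep(U, 2, ranges$high - ranges$low, "*"), 2, ranges$low, "+")
  colnames(Xs) <- ranges$name
  if (constraint) {
    ok <- feasible(Xs, ranges)
    if (!any(ok)) stop("no feasible screen points; check the constraint")
    Xs <- Xs[ok, , drop = FALSE]
  }
  if (final) {
    acq_fun <- function(Xn) gp_posterior(model, Xn)$mean
  } else {
    gmax <- draw_gmax(model, config$n_mc, derive_seed(seed, 17L))
    acq_fun <- function(Xn) nei_given_gmax(model, Xn, gmax)
  }
  vals <- acq_fun(Xs)
  ord <- order(vals, decreasing = TRUE)
  top <- ord[seq_len(min(config$n_polish, length(ord)))]
  best_x <- Xs[top[1], ]
  best_v <- vals[top[1]]
  for (i in top) {
    opt <- tryCatch(stats::optim(
      Xs[i, ],
      fn = function(p) -acq_fun(matrix(p, nrow = 1)),
      method = "L-BFGS-B", lower = ranges$low, upper = ranges$high),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (constraint && !feasible(opt$par, ranges)) next
    if (-opt$value > best_v) {
      best_v <- -opt$value
      best_x <- opt$par
    }
  }
  list(x = stats::setNames(as.numeric(best_x), ranges$name), acq = best_v)
}

eval_oracle <- function(oracle, X, ...) {
  if (inherits(oracle, "truth_model")) return(truth_observe(oracle, X, ...))
  out <- oracle(X)
  if (is.null(dim(out))) out <- data.frame(yield = out)
  as.data.frame(out)
}

#' Run a Bayesian-optimization experiment sequence
#'
#' Evaluates the experiment oracle at the initialization runs, then loops:
#' refit the GP on all objective values so far, propose the next
#' conditions (noisy expected improvement; posterior mean on the final
#' iteration), evaluate, append. Records per-iteration conditions,
#' responses, objective, acquisition value, GP hyperparameters, and the
#' running best objective.
#'
#' @param oracle a `truth_model` (see [make_pilot_truth()]) or a function
#'   mapping a natural-unit condition matrix to a response data.frame.
#' @param init initialization conditions: a `design_matrix` or a
#'   natural-unit matrix/data.frame.
#' @param n_adaptive number of adaptive experiments after initialization.
#' @param weights an [objective_weights()] to build the penalized
#'   objective from `yield`/`kappa`/`viscosity` responses, or `NULL` to
#'   use the single response column directly (simulation mode).
#' @param ranges search box; defaults to the init design's ranges.
#' @param constraint apply the corner-exclusion constraint.
#' @param config a [bo_config()].
#' @param seed integer seed; every refit and proposal derives its own
#'   sub-seed from it.
#' @param noise_seed optional separate seed stream for oracle noise.
#' @return A `bo_trace` data.frame: `iter`, `phase`
#'   (`init`/`adaptive`/`final`), factor columns, response columns,
#'   `objective`, `acq`, `best_so_far`.
#' @export
run_bo <- function(oracle, init, n_adaptive = 10, weights = NULL,
                   ranges = NULL, constraint = !is.null(weights),
                   config = bo_config(), seed = 1, noise_seed = NULL) {
  if (inherits(init, "design_matrix")) {
    if (is.null(ranges)) ranges <- design_ranges(init)
    Xinit <- to_natural(unclass(init), ranges)
  } else {
    if (is.null(ranges)) stop("ranges must be given for a plain init matrix")
    Xinit <- as_point_matrix(init, ranges)
  }
  if (nrow(Xinit) == 0) stop("initialization design is empty")
  if (constraint && !all(feasible(Xinit, ranges)))
    stop("initialization runs must satisfy the feasibility constraint")
  obj_of <- function(resp) {
    if (is.null(weights)) resp[[1]]
    else objective_g(resp$yield, resp$kappa, resp$viscosity, weights)
  }
  resp <- eval_oracle(oracle, Xinit,
                      seed = if (is.null(noise_seed)) derive_seed(seed, 0L)
                             else derive_seed(noise_seed, 0L))
  X <- Xinit
  g <- obj_of(resp)
  n0 <- nrow(Xinit)
  trace <- data.frame(iter = seq_len(n0), phase = "init",
                      as.data.frame(Xinit), resp,
                      objective = g, acq = NA_real_)
  for (i in seq_len(n_adaptive)) {
    model <- fit_gp_map(X, g, bounds = ranges, priors = config$priors,
                        restarts = config$restarts,
                        seed = derive_seed(seed, i, 1L))
    prop <- propose_next(model, ranges, constraint = constraint,
                         final = (i == n_adaptive), config = config,
                         seed = derive_seed(seed, i, 2L))
    xn <- matrix(prop$x, nrow = 1, dimnames = list(NULL, ranges$name))
    ri <- eval_oracle(oracle, xn,
                      seed = if (is.null(noise_seed)) derive_seed(seed, i, 3L)
                             else derive_seed(noise_seed, i, 3L))
    gi <- obj_of(ri)
    X <- rbind(X, xn)
    g <- c(g, gi)
    trace <- rbind(trace, data.frame(
      iter = n0 + i, phase = if (i == n_adaptive) "final" else "adaptive",
      as.data.frame(xn), ri, objective = gi, acq = prop$acq))
  }
  trace$best_so_far <- cummax(trace$objective)
  class(trace) <- c("bo_trace", class(trace))
  trace
}
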