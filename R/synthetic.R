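#' Ground-truth response models for synthetic studies
#'
#' A `truth_model` bundles one or more smooth response surfaces over a
#' natural-unit design box with a declared Gaussian noise model, and acts
#' as the experiment oracle in simulations: `truth_predict()` returns
#' noiseless responses, `truth_observe()` adds seeded measurement noise.
#'
#' @param x a `truth_model`.
#' @param X condition matrix/data.frame in natural units.
#' @param seed integer seed for the noise draws.
#' @param noise_sd named per-response noise standard deviations,
#'   overriding the model's declared noise.
#' @name truth_model
NULL

new_truth_model <- function(fun, ranges, responses, noise_sd, anchors,
                            label) {
  structure(list(fun = fun, ranges = ranges, responses = responses,
                 noise_sd = noise_sd, anchors = anchors, label = label),
            class = "truth_model")
}

#' @rdname truth_model
#' @export
truth_predict <- function(x, X) {
  X <- as_point_matrix(X, x$ranges)
  out <- x$fun(X)
  stopifnot(all(x$responses %in% names(out)))
  out[, x$responses, drop = FALSE]
}

#' @rdname truth_model
#' @export
truth_observe <- function(x, X, seed = 1, noise_sd = x$noise_sd) {
  out <- truth_predict(x, X)
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep_len(noise_sd, length(x$responses)),
                                x$responses)
  noise_sd <- noise_sd[x$responses]
  with_seed(seed, {
    for (j in seq_along(x$responses)) {
      sd_j <- noise_sd[[j]]
      if (is.finite(sd_j) && sd_j > 0)
        out[[j]] <- out[[j]] + stats::rnorm(nrow(out), 0, sd_j)
    }
  })
  out
}

#' @export
print.truth_model <- function(x, ...) {
  cat("Synthetic truth model:", x$label, "\n")
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  cat("  noise sd:", paste(sprintf("%s=%g", x$responses,
                                   x$noise_sd[x$responses]),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Calibrated quadratic extraction-yield surface
#'
#' A full second-order polynomial carbohydrate-extraction yield surface
#' over the extraction box, calibrated by a constrained solve so that its
#' global maximum over the domain is `ymax` percent at `optimum` and the
#' domain-center yield is `ycenter` percent. The surface is
#' `y(x) = ymax - s (x - x*)' A (x - x*)` in coded units: `A` (positive
#' definite, configurable) fixes the shape, and the scale `s` is solved
#' from the center anchor. Because both anchors sit close together near
#' the center, the calibrated curvature is steep and the quadratic
#' extrapolates to strongly negative values at remote corners, as an
#' empirical quadratic fit extrapolated outside its data would.
#'
#' @param ranges [factor_ranges()]; must contain `optimum`.
#' @param ymax maximum yield, percent (default 12.7).
#' @param ycenter yield at the domain center, percent (default 11.8).
#' @param optimum natural-unit location of the maximum
#'   (default 172 degC, 97 min, ratio 6).
#' @param shape positive-definite 3x3 curvature shape matrix in coded
#'   units.
#' @param noise_sd measurement noise sd in yield percentage points.
#' @return A `truth_model` with response `yield`; the Eq.-style coded
#'   polynomial coefficients are attached as `$coefficients`.
#' @export
make_extraction_truth <- function(ranges = extraction_ranges(),
                                  ymax = 12.7, ycenter = 11.8,
                                  optimum = c(172, 97, 6),
                                  shape = default_extraction_shape(),
                                  noise_sd = 0) {
  if (any(optimum < ranges$low) || any(optimum > ranges$high))
    stop("calibration error: the optimum must lie inside the factor ranges")
  xs <- drop(to_coded(optimum, ranges))
  qc <- drop(xs %*% shape %*% xs)
  if (qc <= 0)
    stop("calibration error: optimum coincides with the domain center, ",
         "so the center anchor cannot be satisfied")
  if (ycenter >= ymax)
    stop("calibration error: center yield must be below the maximum")
  if (any(eigen(shape, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("shape matrix must be positive definite")
  s <- (ymax - ycenter) / qc
  fun <- function(X) {
    Z <- sweep(to_coded(X, ranges), 2, xs, "-")
    data.frame(yield = ymax - s * rowSums((Z %*% shape) * Z))
  }
  tm <- new_truth_model(fun, ranges, "yield",
                        c(yield = noise_sd),
                        anchors = list(max_value = ymax,
                                       argmax = stats::setNames(optimum,
                                                                ranges$name),
                                       center_value = ycenter),
                        label = "extraction quadratic")
  H <- -s * shape
  nm <- ranges$name
  coefs <- c(intercept = ymax - s * qc,
             stats::setNames(drop(-2 * H %*% xs), nm))
  for (i in 1:2) for (j in (i + 1):3)
    coefs[paste0(nm[i], ":", nm[j])] <- 2 * H[i, j]
  coefs[paste0(nm, "^2")] <- diag(H)
  tm$coefficients <- coefs
  tm
}

#' @rdname make_extraction_truth
#' @export
default_extraction_shape <- function() {
  A <- matrix(c(6, 0.5, 0.2,
                0.5, 12, 0.3,
                0.2, 0.3, 1), 3, 3, byrow = TRUE)
  (A + t(A)) / 2
}

#' Pilot delignification response surfaces
#'
#' Smooth synthetic ground truth for the three pulp responses over the
#' delignification box. Each response decreases strictly with a digestion
#' severity variable `s = wT (T - 120)/40 + wt (tau - 60)/120` via a
#' logistic decay (deliberately non-quadratic, so a comparison of
#' quadratic and GP surrogates is not rigged in favor of the quadratic).
#' The severity weights differ per response, reflecting that cellulose
#' depolymerization (viscosity loss) is most temperature-sensitive while
#' delignification (kappa reduction) benefits most from long times:
#' cellulose yield holds a plateau at low severity (its maximum, at the
#' low-severity, high-ratio corner, is calibrated to `ymax` percent) and
#' then falls off sigmoidally once delignification transitions into
#' cellulose degradation, with a small bonus in liquid-to-solid ratio;
#' kappa number decays steeply from ~44 to ~2; viscosity decays from
#' ~900 to ~330 mL/g.
#' Under the penalized objective of [objective_g()] the optimum lands at
#' moderate temperature, long time, and maximum ratio, with yields there
#' in the low-to-mid 50s.
#'
#' @param ranges [factor_ranges()] of the pilot box.
#' @param ymax maximum cellulose yield over the box, percent.
#' @param noise_sd named noise standard deviations per response.
#' @return A `truth_model` with responses `yield`, `kappa`, `viscosity`.
#' @export
make_pilot_truth <- function(ranges = pilot_ranges(), ymax = 56.3,
                             noise_sd = c(yield = 0.4, kappa = 0.25,
                                          viscosity = 8)) {
  yd <- 9; ym <- 1.35; ysl <- 4.5; rb <- 1.8
  c0 <- ymax - yd * stats::plogis(ysl * ym) - rb
  fun <- function(X) {
    sT <- (X[, 1] - ranges$low[1]) / (ranges$high[1] - ranges$low[1])
    st <- (X[, 2] - ranges$low[2]) / (ranges$high[2] - ranges$low[2])
    r <- (X[, 3] - ranges$low[3]) / (ranges$high[3] - ranges$low[3])
    data.frame(
      yield = c0 + yd * stats::plogis(-ysl * (1.1 * sT + 0.9 * st - ym)) +
        rb * r,
      kappa = 2.2 + 42 * stats::plogis(-4.5 * (0.9 * sT + 1.1 * st - 0.9)),
      viscosity = 280 +
        640 * stats::plogis(-3 * (1.3 * sT + 0.7 * st - 1.05)))
  }
  new_truth_model(fun, ranges, c("yield", "kappa", "viscosity"), noise_sd,
                  anchors = list(max_yield = ymax,
                                 yield_argmax = stats::setNames(
                                   c(ranges$low[1], ranges$low[2],
                                     ranges$high[3]), ranges$name)),
                  label = "pilot delignification surfaces")
}

#' Cellulose yield from raw pulp measurements
#'
#' Cellulose yield is the screened pulp yield after subtracting the
#' lignin and hemicellulose fractions of the pulp: lignin percent is
#' estimated as `kappa / 6.57` and hemicellulose percent as
#' `100 - alkali resistance`, both interpreted as percentages of the
#' screened pulp mass, so
#' `cellulose = screened_yield * (100 - lignin - hemicellulose) / 100`.
#'
#' @param screened_yield gravimetric screened pulp yield, percent of wood.
#' @param kappa kappa number.
#' @param alkali_resistance alkali resistance, percent (<= 100).
#' @param conversion kappa-to-lignin conversion factor (default 6.57).
#' @return Cellulose yield, percent of wood.
#' @examples
#' cellulose_yield(60, 6.57, 95)  # 60 * (100 - 1 - 5) / 100 = 56.4
#' @export
cellulose_yield <- function(screened_yield, kappa, alkali_resistance,
                            conversion = 6.57) {
  if (any(screened_yield < 0) || any(kappa < 0))
    stop("pulp measurements must be nonnegative")
  if (any(alkali_resistance > 100) || any(alkali_resistance < 0))
    stop("alkali resistance must be in [0, 100]")
  lignin <- kappa / conversion
  hemi <- 100 - alkali_resistance
  frac <- (100 - lignin - hemi) / 100
  if (any(frac < 0))
    stop("computed cellulose fraction is negative; check the measurements")
  screened_yield * frac
}

#' Simulate an experiment table from a truth model
#'
#' Evaluates the ground truth at the design points and adds seeded
#' Gaussian measurement noise, producing a natural-unit experiment table.
#'
#' @param truth a `truth_model`.
#' @param design a `design_matrix` or natural-unit condition matrix.
#' @param noise_sd named per-response noise sd (defaults to the truth
#'   model's declared noise; use 0 for noiseless tables).
#' @param seed integer seed.
#' @return A data.frame with one column per factor (natural units) plus
#'   the response columns.
#' @export
generate_table <- function(truth, design, noise_sd = truth$noise_sd,
                           seed = 1) {
  ranges <- truth$ranges
  X <- if (inherits(design, "design_matrix"))
    to_natural(unclass(design), design_ranges(design))
  else as_point_matrix(design, ranges)
  resp <- truth_observe(truth, X, seed = seed, noise_sd = noise_sd)
  cbind(as.data.frame(X), resp)
}
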