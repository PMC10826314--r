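#' Assign experiments to evaluation regions
#'
#' Three row-wise regions are used to compare models across the design
#' space: `all` (every experiment), `target` (measured kappa at or below
#' its target and viscosity inside the dissolving-pulp window), and
#' `near_optimum` (long digestion times at moderate temperatures, the
#' neighbourhood of the process optimum).
#'
#' @param table experiment table with `temperature`, `time`, `kappa`,
#'   `viscosity` columns.
#' @param kappa_max target kappa ceiling (default 6.57).
#' @param visc_low,visc_high viscosity window (400, 600 mL/g).
#' @param time_min,temp_window near-optimum rule: `time > time_min` and
#'   temperature within `temp_window` (defaults 110 min, 130--150 degC).
#' @return A named list of logical masks (`all`, `target`,
#'   `near_optimum`) with a `counts` attribute.
#' @export
assign_regions <- function(table, kappa_max = 6.57, visc_low = 400,
                           visc_high = 600, time_min = 110,
                           temp_window = c(130, 150)) {
  need <- c("temperature", "time", "kappa", "viscosity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("experiment table is missing columns: ",
         paste(miss, collapse = ", "))
  masks <- list(
    all = rep(TRUE, nrow(table)),
    target = table$kappa <= kappa_max &
      table$viscosity >= visc_low & table$viscosity <= visc_high,
    near_optimum = table$time > time_min &
      table$temperature >= temp_window[1] &
      table$temperature <= temp_window[2])
  attr(masks, "counts") <- vapply(masks, sum, integer(1))
  masks
}

## rows of `points` matching rows of `train` on the factor columns;
## with exclusive = TRUE each training row is consumed at most once, so
## replicate runs at a repeated condition pair up one-to-one
match_conditions <- function(points, train, factor_names, tol = 1e-8,
                             exclusive = FALSE) {
  A <- as.matrix(points[, factor_names, drop = FALSE])
  B <- as.matrix(train[, factor_names, drop = FALSE])
  used <- logical(nrow(B))
  vapply(seq_len(nrow(A)), function(i) {
    hits <- which(rowSums(abs(sweep(B, 2, A[i, ], "-"))) < tol)
    if (exclusive) {
      free <- hits[!used[hits]]
      if (length(free)) hits <- free
    }
    if (!length(hits)) return(NA_integer_)
    used[hits[1]] <<- TRUE
    hits[1]
  }, integer(1))
}

#' Region-wise leave-one-out RMSE comparison of yield models
#'
#' Compares a second-order regression model and a GP regression model of
#' cellulose yield. Each model is trained on its own 15 experiments; RMSE
#' is computed over all evaluation locations and per region. At a
#' location inside a model's training set the prediction is
#' leave-one-out: the linear model keeps its selected terms and refits
#' the coefficients without that row (hat-diagonal shortcut), the GP
#' re-estimates its MAP hyperparameters without that row. Outside the
#' training set a full-model prediction is used (extrapolation is
#' permitted).
#'
#' @param linear_train training table for the quadratic model (the
#'   classical design runs).
#' @param gp_train training table for the GP model (initialization plus
#'   adaptive runs), fitted to yield without penalty terms.
#' @param all_points evaluation table containing the union of locations,
#'   with measured `yield` plus the `kappa`/`viscosity` columns used by
#'   the region rules.
#' @param ranges [factor_ranges()] of the study.
#' @param response response column (default `"yield"`).
#' @param alpha backward-elimination significance level for the linear
#'   model.
#' @param config a [bo_config()] supplying the GP priors/restarts.
#' @param seed integer seed for the GP refits.
#' @param linear_exclude rows of `linear_train` to exclude from the
#'   linear fit (e.g. flagged outliers).
#' @return A list with `rmse` (model x region matrix; regions with zero
#'   members are `NA`), `counts`, and `predictions` (per-location
#'   predictions of both models with a `loo` flag per model).
#' @export
loocv_rmse_comparison <- function(linear_train, gp_train, all_points,
                                  ranges, response = "yield",
                                  alpha = 0.10, config = bo_config(),
                                  seed = 1, linear_exclude = integer(0)) {
  fn <- ranges$name
  y_all <- all_points[[response]]
  n <- nrow(all_points)

  ## --- linear model: fit + hierarchical backward elimination
  lin_fit <- backward_eliminate(
    fit_second_order(linear_train, response, ranges,
                     exclude = linear_exclude), alpha)
  lin_rows <- match_conditions(all_points, linear_train, fn, exclusive = TRUE)
  kept <- setdiff(seq_len(nrow(linear_train)), linear_exclude)
  lin_pred <- predict_with_se(lin_fit, all_points[, fn])$mean
  lin_loo <- rep(FALSE, n)
  for (i in seq_len(n)) {
    r <- lin_rows[i]
    if (is.na(r) || !(r %in% kept)) next
    j <- match(r, kept)  # position within the fitted rows
    lin_pred[i] <- lin_fit$y[j] - lin_fit$residuals[j] / (1 - lin_fit$hat[j])
    lin_loo[i] <- TRUE
  }

  ## --- GP model: full fit + per-fold MAP re-estimation
  Xg <- as.matrix(gp_train[, fn])
  yg <- gp_train[[response]]
  gp_full <- fit_gp_map(Xg, yg, bounds = ranges, priors = config$priors,
                        restarts = config$restarts,
                        seed = derive_seed(seed, 1L))
  gp_rows <- match_conditions(all_points, gp_train, fn, exclusive = TRUE)
  gp_pred <- gp_posterior(gp_full, as.matrix(all_points[, fn]))$mean
  gp_loo <- rep(FALSE, n)
  for (i in seq_len(n)) {
    r <- gp_rows[i]
    if (is.na(r)) next
    fold <- fit_gp_map(Xg[-r, , drop = FALSE], yg[-r], bounds = ranges,
                       priors = config$priors, restarts = config$restarts,
                       seed = derive_seed(seed, 2L, r))
    gp_pred[i] <- gp_posterior(fold, Xg[r, , drop = FALSE])$mean
    gp_loo[i] <- TRUE
  }

  masks <- assign_regions(all_points)
  rmse <- sapply(masks, function(m) {
    if (!any(m)) return(c(linear = NA_real_, gp = NA_real_))
    c(linear = sqrt(mean((lin_pred[m] - y_all[m])^2)),
      gp = sqrt(mean((gp_pred[m] - y_all[m])^2)))
  })
  list(rmse = rmse, counts = attr(masks, "counts"),
       predictions = data.frame(all_points[, fn], observed = y_all,
                                linear = lin_pred, linear_loo = lin_loo,
                                gp = gp_pred, gp_loo = gp_loo),
       linear_fit = lin_fit, gp_fit = gp_full)
}
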