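#' Simulation study grid
#'
#' Defines the factorial grid of the initialization/noise simulation
#' study: initialization sizes, measurement-noise levels (standard
#' deviation in yield percentage points), repetitions per cell, sequence
#' length, and the base seed from which every cell derives its own
#' reproducible seed. The default grid is 5 sizes x 3 noise levels x 200
#' repetitions of 20-experiment sequences (3000 sequences, 60,000
#' simulated experiments).
#'
#' @param sizes initialization sizes, a subset of 4..8.
#' @param noise noise standard deviations in percentage points.
#' @param reps repetitions per (size, noise) cell.
#' @param length total experiments per sequence (> max size).
#' @param seed base seed.
#' @return A list of class `study_grid`.
#' @export
study_grid <- function(sizes = 4:8, noise = c(0, 0.25, 0.5), reps = 200,
                       length = 20, seed = 1) {
  if (!all(sizes %in% 4:8)) stop("initialization sizes must be within 4..8")
  if (any(noise < 0)) stop("noise standard deviations must be nonnegative")
  if (length <= max(sizes))
    stop("sequence length must exceed the largest initialization size")
  if (reps < 1) stop("reps must be >= 1")
  structure(list(sizes = as.integer(sizes), noise = as.numeric(noise),
                 reps = as.integer(reps), length = as.integer(length),
                 seed = as.integer(seed)), class = "study_grid")
}

#' Sequence and experiment counts of a study grid
#'
#' Bookkeeping derived from the grid without executing it.
#'
#' @param grid a [study_grid()].
#' @return A list with `n_cells`, `n_sequences`, and `n_experiments`
#'   (`sequences x length`).
#' @export
study_size <- function(grid) {
  n_seq <- length(grid$sizes) * length(grid$noise) * grid$reps
  list(n_cells = length(grid$sizes) * length(grid$noise),
       n_sequences = n_seq,
       n_experiments = n_seq * grid$length)
}

#' Simulate one Bayesian-optimization experiment sequence
#'
#' Runs a single sequence against a ground-truth yield surface:
#' observations are truth plus seeded Gaussian noise, the GP is fitted on
#' the noisy observations, adaptive conditions are proposed by the
#' optimization loop (raw yield objective, no feasibility constraint),
#' and the best-so-far curve is tracked on the *noiseless* truth values
#' of the visited conditions.
#'
#' @param truth a single-response `truth_model`.
#' @param init a `design_matrix` of initialization runs.
#' @param noise_sd measurement-noise standard deviation (percentage
#'   points).
#' @param length total number of experiments (including initialization).
#' @param seed integer seed; identical seeds reproduce the sequence.
#' @param config a [bo_config()].
#' @return A list with `best_so_far` (noiseless, per step) and the full
#'   `trace`.
#' @export
simulate_sequence <- function(truth, init, noise_sd, length, seed = 1,
                              config = bo_config()) {
  n0 <- nrow(init)
  if (length < n0) stop("sequence length must cover the initialization")
  truth$noise_sd <- stats::setNames(rep_len(noise_sd,
                                            base::length(truth$responses)),
                                    truth$responses)
  trace <- run_bo(truth, init, n_adaptive = length - n0, weights = NULL,
                  ranges = truth$ranges, constraint = FALSE,
                  config = config, seed = seed)
  noiseless <- truth_predict(truth, trace[, truth$ranges$name])[[1]]
  list(best_so_far = cummax(noiseless), trace = trace)
}

#' Run the initialization/noise simulation study
#'
#' For each initialization size, enumerates the G-efficiency-optimal
#' subsets of the candidate locations (main-effect model) and splits each
#' cell's repetitions as evenly as possible across the tied optimal
#' designs (earlier designs, in lexicographic candidate order, receive
#' the extra repetitions). Every repetition simulates one sequence with
#' its own derived seed.
#'
#' @param truth a single-response `truth_model` (the experiment oracle).
#' @param candidates a `design_matrix` of admissible initialization
#'   locations (the 15 unique CCF locations by default).
#' @param grid a [study_grid()].
#' @param config a [bo_config()].
#' @return A `study_result` data.frame in long format: `init_size`,
#'   `noise_sd`, `rep`, `design_id`, `step`, `best_so_far`.
#' @export
run_study <- function(truth, candidates = ccf_candidates(truth$ranges),
                      grid = study_grid(), config = bo_config()) {
  out <- vector("list", 0)
  for (size in grid$sizes) {
    sel <- select_g_optimal_subsets(candidates, size)
    n_designs <- length(sel$subsets)
    for (ni in seq_along(grid$noise)) {
      noise_sd <- grid$noise[ni]
      for (rep in seq_len(grid$reps)) {
        design_id <- ((rep - 1L) %% n_designs) + 1L
        idx <- sel$subsets[[design_id]]
        init <- new_design_matrix(
          unclass(candidates)[idx, , drop = FALSE],
          design_ranges(candidates))
        seq_seed <- derive_seed(grid$seed, size, ni, rep)
        sim <- simulate_sequence(truth, init, noise_sd, grid$length,
                                 seed = seq_seed, config = config)
        out[[length(out) + 1L]] <- data.frame(
          init_size = size, noise_sd = noise_sd, rep = rep,
          design_id = design_id, step = seq_len(grid$length),
          best_so_far = sim$best_so_far)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_result", class(res))
  res
}

#' Convergence summary of a study result
#'
#' Per-cell, per-step empirical quantiles and mean of the best-so-far
#' noiseless yield, in the shape needed for convergence-panel plots.
#'
#' @param result a `study_result` from [run_study()].
#' @param quantiles probabilities to report.
#' @return A data.frame keyed by `init_size`, `noise_sd`, `step` with a
#'   `mean` column and one `q<prob>` column per quantile.
#' @export
summarize_convergence <- function(result,
                                  quantiles = c(0.05, 0.25, 0.5,
                                                0.75, 0.95)) {
  if (!nrow(result)) stop("empty study result")
  key <- interaction(result$init_size, result$noise_sd, result$step,
                     drop = TRUE)
  rows <- lapply(split(result, key), function(d) {
    q <- stats::quantile(d$best_so_far, quantiles, names = FALSE)
    cbind(d[1, c("init_size", "noise_sd", "step")],
          mean = mean(d$best_so_far),
          stats::setNames(as.data.frame(t(q)),
                          paste0("q", format(quantiles))))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$init_size, out$noise_sd, out$step), ]
  rownames(out) <- NULL
  out
}

#' First step reaching a fraction of the true maximum
#'
#' For each simulated sequence, the first experiment index whose
#' best-so-far noiseless yield reaches `frac` times the truth maximum
#' (`Inf` when never reached within the sequence).
#'
#' @param result a `study_result`.
#' @param truth_max the known maximum of the truth surface.
#' @param frac target fraction (default 0.99).
#' @return A data.frame per sequence: `init_size`, `noise_sd`, `rep`,
#'   `step_reached`.
#' @export
steps_to_fraction <- function(result, truth_max, frac = 0.99) {
  key <- interaction(result$init_size, result$noise_sd, result$rep,
                     drop = TRUE)
  rows <- lapply(split(result, key), function(d) {
    d <- d[order(d$step), ]
    hit <- which(d$best_so_far >= frac * truth_max)
    data.frame(init_size = d$init_size[1], noise_sd = d$noise_sd[1],
               rep = d$rep[1],
               step_reached = if (length(hit)) d$step[hit[1]] else Inf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
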