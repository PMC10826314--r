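# shared fixtures: a unit test box, a gentle concave quadratic oracle,
# and a coded quadratic data generator for regression tests

unit_ranges <- function() {
  factor_ranges(c("temperature", "time", "ratio"),
                low = c(0, 0, 0), high = c(1, 1, 1))
}

# concave single-peak quadratic over the pilot box, known maximum
gentle_peak <- function(ranges = pilot_ranges(),
                        peak = c(135, 150, 8), height = 10) {
  force(ranges); force(peak); force(height)
  function(X) {
    Z <- to_coded(X, ranges) - matrix(to_coded(peak, ranges),
                                      nrow(X), 3, byrow = TRUE)
    data.frame(yield = height - rowSums(Z^2))
  }
}

# experiment table from a known coded-unit quadratic (for fit recovery)
quadratic_table <- function(beta, ranges = pilot_ranges(), noise = 0,
                            seed = 1) {
  des <- ccf_design(3, 3, ranges)
  coded <- unclass(des)
  X <- spec_model_matrix_for_test(coded, ranges$name)
  y <- drop(X %*% beta)
  if (noise > 0) y <- y + with_seed_test(seed, rnorm(length(y), 0, noise))
  cbind(as.data.frame(to_natural(coded, ranges)), yield = y)
}

# independent model-matrix builder (kept separate from the package's so
# oracle tests do not share its code path)
spec_model_matrix_for_test <- function(coded, nm) {
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cbind(1, x1, x2, x3, x1 * x2, x1 * x3, x2 * x3, x1^2, x2^2, x3^2)
}

with_seed_test <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
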