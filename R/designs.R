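#' Factor ranges for a three-factor study
#'
#' Defines the natural-unit design box for a set of process factors. Each
#' factor is described by a name and a low/high bound; coded units rescale
#' the interval `[low, high]` affinely onto `[-1, 1]`.
#'
#' @param names character vector of factor names.
#' @param low,high numeric vectors of lower and upper bounds in natural
#'   units; `low < high` elementwise.
#' @return An object of class `factor_ranges`: a data.frame with columns
#'   `name`, `low`, `high`.
#' @examples
#' pilot_ranges()
#' @export
factor_ranges <- function(names, low, high) {
  stopifnot(length(names) == length(low), length(low) == length(high))
  if (any(!is.finite(low)) || any(!is.finite(high)))
    stop("factor bounds must be finite")
  if (any(low >= high))
    stop("each factor must satisfy low < high")
  out <- data.frame(name = as.character(names), low = as.numeric(low),
                    high = as.numeric(high), stringsAsFactors = FALSE)
  class(out) <- c("factor_ranges", "data.frame")
  out
}

#' @rdname factor_ranges
#' @details `pilot_ranges()` gives the delignification study box:
#'   temperature 120--160 degC, time 60--180 min, liquid-to-solid ratio
#'   5--10. `extraction_ranges()` gives the default box for the
#'   carbohydrate-extraction surface: temperature 150--190 degC, time
#'   40--160 min, ratio 4--8.
#' @export
pilot_ranges <- function() {
  factor_ranges(c("temperature", "time", "ratio"),
                low = c(120, 60, 5), high = c(160, 180, 10))
}

#' @rdname factor_ranges
#' @export
extraction_ranges <- function() {
  factor_ranges(c("temperature", "time", "ratio"),
                low = c(150, 40, 4), high = c(190, 160, 8))
}

range_mid <- function(ranges) (ranges$low + ranges$high) / 2
range_half <- function(ranges) (ranges$high - ranges$low) / 2

as_point_matrix <- function(x, ranges) {
  if (is.data.frame(x)) x <- as.matrix(x[, ranges$name, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(ranges))
    stop("point has ", ncol(x), " columns but ", nrow(ranges),
         " factors are defined")
  storage.mode(x) <- "double"
  colnames(x) <- ranges$name
  x
}

#' Convert between natural and coded units
#'
#' `to_coded()` maps natural-unit conditions onto coded units so that
#' `low -> -1`, `high -> +1` and the range midpoint maps to 0;
#' `to_natural()` is the exact inverse. Points outside the design box map
#' outside `[-1, 1]` and are permitted.
#'
#' @param x a numeric vector (one point), matrix, or data.frame of points;
#'   columns in factor order.
#' @param ranges a [factor_ranges()] object.
#' @return A matrix of the same shape with converted coordinates.
#' @examples
#' to_coded(c(140, 120, 7.5), pilot_ranges())
#' @export
to_coded <- function(x, ranges) {
  x <- as_point_matrix(x, ranges)
  sweep(sweep(x, 2, range_mid(ranges), "-"), 2, range_half(ranges), "/")
}

#' @rdname to_coded
#' @export
to_natural <- function(x, ranges) {
  x <- as_point_matrix(x, ranges)
  sweep(sweep(x, 2, range_half(ranges), "*"), 2, range_mid(ranges), "+")
}

new_design_matrix <- function(coded, ranges, replicate = NULL) {
  coded <- as_point_matrix(coded, ranges)
  if (is.null(replicate)) replicate <- rep(1L, nrow(coded))
  structure(coded, ranges = ranges, replicate = as.integer(replicate),
            class = c("design_matrix", class(coded)))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design with", nrow(x), "runs in coded units\n")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

design_ranges <- function(design) attr(design, "ranges")

#' Three-factor Box-Behnken design
#'
#' Generates the 3-factor Box-Behnken design in coded units: all 12 edge
#' midpoints of the factor cube (exactly one factor at 0, the other two at
#' +/-1) plus `n_center` replicated center runs.
#'
#' @param n_factors number of factors; only 3 is supported.
#' @param n_center number of center-point replicates (>= 1).
#' @param ranges optional [factor_ranges()] attached for unit conversion;
#'   defaults to [pilot_ranges()].
#' @return A `design_matrix` of `12 + n_center` rows.
#' @examples
#' nrow(box_behnken(3, 3))  # 15 runs
#' @export
box_behnken <- function(n_factors = 3, n_center = 3, ranges = pilot_ranges()) {
  if (n_factors != 3)
    stop("box_behnken supports exactly 3 factors (requested ", n_factors, ")")
  if (n_center < 1) stop("n_center must be >= 1")
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  blocks <- list(cbind(0, pm[, 1], pm[, 2]),
                 cbind(pm[, 1], 0, pm[, 2]),
                 cbind(pm[, 1], pm[, 2], 0))
  coded <- rbind(do.call(rbind, blocks),
                 matrix(0, n_center, 3))
  rep_tag <- c(rep(1L, 12), seq_len(n_center))
  new_design_matrix(coded, ranges, rep_tag)
}

#' Three-factor face-centered central composite design
#'
#' Generates the CCF design in coded units: the 8 cube corners, the 6 face
#' centers (+/-1 on one axis, 0 elsewhere), and `n_center` center
#' replicates. All coordinates are in `{-1, 0, 1}`.
#'
#' @inheritParams box_behnken
#' @return A `design_matrix` of `14 + n_center` rows (15 unique locations
#'   when `n_center >= 1`).
#' @examples
#' d <- ccf_design(3, 3)
#' nrow(unique(unclass(d)))  # 15 unique locations
#' @export
ccf_design <- function(n_factors = 3, n_center = 3,
                       ranges = extraction_ranges()) {
  if (n_factors != 3)
    stop("ccf_design supports exactly 3 factors (requested ", n_factors, ")")
  if (n_center < 1) stop("n_center must be >= 1")
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  faces <- rbind(diag(3), -diag(3))
  coded <- rbind(corners, faces, matrix(0, n_center, 3))
  rep_tag <- c(rep(1L, 14), seq_len(n_center))
  new_design_matrix(coded, ranges, rep_tag)
}

#' Candidate set of unique CCF locations
#'
#' The 15 unique sampling locations of the three-factor CCF design
#' (8 corners, 6 face centers, 1 center), used as the admissible
#' initialization locations in the simulation study.
#'
#' @param ranges attached [factor_ranges()].
#' @return A `design_matrix` of 15 unique rows, ordered corners, faces,
#'   center.
#' @export
ccf_candidates <- function(ranges = extraction_ranges()) {
  d <- ccf_design(3, 1, ranges)
  new_design_matrix(unclass(d)[seq_len(15), , drop = FALSE], ranges)
}

## Model matrix for a term-spec on coded coordinates. `model` is either
## "main" (intercept + linear terms) or a character vector of labels drawn
## from: "intercept", factor names, "a:b" interactions, "a^2" quadratics.
spec_model_matrix <- function(coded, model = "main", names = colnames(coded)) {
  coded <- as.matrix(coded)
  if (identical(model, "main"))
    model <- c("intercept", names)
  cols <- lapply(model, function(term) {
    if (term == "intercept") return(rep(1, nrow(coded)))
    if (grepl(":", term, fixed = TRUE)) {
      f <- strsplit(term, ":", fixed = TRUE)[[1]]
      return(coded[, f[1]] * coded[, f[2]])
    }
    if (grepl("^2", term, fixed = TRUE)) {
      f <- sub("\\^2$", "", term)
      return(coded[, f]^2)
    }
    coded[, term]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- model
  m
}

#' G-efficiency of a design over a candidate set
#'
#' Computes `100 * (p / N) / d_max`, where `p` is the number of model
#' terms, `N` the number of design runs, and `d_max` the maximum over the
#' candidate locations of the prediction-variance leverage
#' `f'(F'F)^{-1} f` under the given term specification. A design that is
#' G-optimal within the candidate set attains 100; any design whose rows
#' are all candidates scores at most 100.
#'
#' @param design a `design_matrix` (coded units).
#' @param candidates a `design_matrix` of admissible locations.
#' @param model term specification; `"main"` (default) is intercept plus
#'   linear main effects.
#' @return The efficiency percentage in `(0, 100]`. A rank-deficient
#'   design returns 0 with attribute `singular = TRUE`.
#' @export
g_efficiency <- function(design, candidates, model = "main") {
  nm <- colnames(design)
  F_ <- spec_model_matrix(design, model, nm)
  p <- ncol(F_)
  if (nrow(F_) < p || qr(F_)$rank < p) {
    return(structure(0, singular = TRUE))
  }
  XtXi <- chol2inv(chol(crossprod(F_)))
  Fc <- spec_model_matrix(candidates, model, nm)
  lev <- rowSums((Fc %*% XtXi) * Fc)
  structure(100 * (p / nrow(F_)) / max(lev), singular = FALSE)
}

#' G-optimal initialization subsets of a candidate set
#'
#' Exhaustively enumerates all `k`-subsets of the candidate locations and
#' returns every subset whose G-efficiency is within a relative tolerance
#' of the maximum, in deterministic lexicographic order of candidate
#' indices. Used to pick initialization runs for Bayesian optimization.
#'
#' @param candidates a `design_matrix` of admissible locations.
#' @param k subset size (`k >= p`, the number of model terms).
#' @param model term specification, as in [g_efficiency()].
#' @param tol relative tolerance for ties on the maximum efficiency.
#' @return A list with elements `subsets` (list of integer index vectors),
#'   `efficiency` (the shared maximal G-efficiency), and `k`.
#' @export
select_g_optimal_subsets <- function(candidates, k, model = "main",
                                     tol = 1e-6) {
  n <- nrow(candidates)
  if (k > n) stop("k = ", k, " exceeds the ", n, " candidate locations")
  nm <- colnames(candidates)
  Fc <- spec_model_matrix(candidates, model, nm)
  p <- ncol(Fc)
  if (k < p) stop("k = ", k, " is below the ", p, " model terms")
  combos <- utils::combn(n, k)
  eff <- apply(combos, 2, function(idx) {
    F_ <- Fc[idx, , drop = FALSE]
    if (qr(F_)$rank < p) return(0)
    XtXi <- chol2inv(chol(crossprod(F_)))
    lev <- rowSums((Fc %*% XtXi) * Fc)
    100 * (p / k) / max(lev)
  })
  best <- max(eff)
  keep <- which(eff >= best * (1 - tol))
  list(subsets = lapply(keep, function(j) combos[, j]),
       efficiency = best, k = k)
}

#' Read or write a design as CSV
#'
#' Designs are exchanged as CSV with one column per factor in natural
#' units plus a `coded_<name>` column set; factor ranges travel in a
#' companion config (see [read_run_config()]).
#'
#' @param design a `design_matrix`.
#' @param path file path.
#' @param ranges for `read_design_csv`, the [factor_ranges()] used to
#'   validate the coded columns.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `design_matrix`.
#' @export
write_design_csv <- function(design, path) {
  ranges <- design_ranges(design)
  nat <- to_natural(unclass(design), ranges)
  coded <- unclass(design)
  colnames(coded) <- paste0("coded_", colnames(coded))
  utils::write.csv(cbind(as.data.frame(nat), as.data.frame(coded)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, ranges) {
  df <- utils::read.csv(path)
  coded_cols <- paste0("coded_", ranges$name)
  if (!all(coded_cols %in% names(df)))
    stop("design CSV is missing coded columns: ",
         paste(setdiff(coded_cols, names(df)), collapse = ", "))
  coded <- as.matrix(df[, coded_cols])
  colnames(coded) <- ranges$name
  new_design_matrix(coded, ranges)
}
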