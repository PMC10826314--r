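#' Second-order term specification
#'
#' Builds the ordered term list of a full quadratic response-surface model
#' in `k = 3` factors: intercept, linear terms, pairwise interactions
#' (i < j), and pure quadratic terms (10 terms in total).
#'
#' @param ranges a [factor_ranges()] object supplying factor names.
#' @return Character vector of term labels, e.g. `"temperature:time"`,
#'   `"time^2"`.
#' @export
full_second_order <- function(ranges) {
  nm <- ranges$name
  k <- length(nm)
  inter <- character(0)
  for (i in seq_len(k - 1))
    for (j in seq((i + 1), k))
      inter <- c(inter, paste0(nm[i], ":", nm[j]))
  c("intercept", nm, inter, paste0(nm, "^2"))
}

term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE))
    return(strsplit(term, ":", fixed = TRUE)[[1]])
  if (grepl("^2", term, fixed = TRUE)) return(sub("\\^2$", "", term))
  character(0)
}

is_linear_term <- function(term, factor_names) term %in% factor_names

#' Fit a second-order response-surface model
#'
#' Ordinary least squares on the coded model matrix of a quadratic
#' polynomial, with the prediction diagnostics used in design-of-
#' experiments practice: PRESS leave-one-out residuals, predictive R
#' squared, hat diagonals, and externally studentized residuals. The
#' response may optionally be modelled on the log10 scale (used for kappa
#' number, whose variation is multiplicative).
#'
#' @param table a data.frame of experiments in natural units, with one
#'   column per factor of `ranges` plus the response column.
#' @param response name of the response column.
#' @param ranges [factor_ranges()] for natural-to-coded conversion.
#' @param transform `"none"` or `"log10"`.
#' @param terms term labels as from [full_second_order()] (the default).
#' @param exclude integer indices of rows to drop (e.g. flagged outliers).
#' @return An object of class `rsm_fit` with components `coefficients`,
#'   `se`, `t`, `p`, `sigma2`, `hat`, `rstudent`, `r_squared`,
#'   `r_squared_pred`, `press`, `df_total`, `df_model`, `df_residual`,
#'   `terms`, `transform`, `excluded`, and the training data.
#' @export
fit_second_order <- function(table, response, ranges,
                             transform = c("none", "log10"),
                             terms = full_second_order(ranges),
                             exclude = integer(0)) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(table))
  keep <- setdiff(seq_len(nrow(table)), exclude)
  tab <- table[keep, , drop = FALSE]
  y <- tab[[response]]
  if (transform == "log10") {
    if (any(y <= 0))
      stop("log10 transform requires a strictly positive response")
    y <- log10(y)
  }
  coded <- to_coded(tab[, ranges$name, drop = FALSE], ranges)
  X <- spec_model_matrix(coded, terms, ranges$name)
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("need more rows (", n, ") than model terms (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    piv <- qx$pivot[seq_len(qx$rank)]
    stop("singular model matrix; collinear terms: ",
         paste(terms[-piv], collapse = ", "))
  }
  XtXi <- chol2inv(qr.R(qx))
  beta <- drop(XtXi %*% crossprod(X, y))
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  se <- sqrt(diag(XtXi) * sigma2)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  h <- rowSums((X %*% XtXi) * X)
  press_res <- res / (1 - h)
  sst <- sum((y - mean(y))^2)
  ## externally studentized residuals: leave-one-out variance estimate
  rstud <- if (df_res > 1) {
    s2_i <- (sum(res^2) - res^2 / (1 - h)) / (df_res - 1)
    res / sqrt(s2_i * (1 - h))
  } else rep(NA_real_, n)
  structure(list(
    coefficients = stats::setNames(beta, terms),
    se = stats::setNames(se, terms),
    t = stats::setNames(tstat, terms),
    p = stats::setNames(pval, terms),
    sigma2 = sigma2,
    hat = h,
    residuals = res,
    rstudent = rstud,
    press = sum(press_res^2),
    r_squared = 1 - sum(res^2) / sst,
    r_squared_pred = 1 - sum(press_res^2) / sst,
    df_total = n - 1, df_model = p - 1, df_residual = df_res,
    terms = terms, transform = transform, response = response,
    ranges = ranges, XtXi = XtXi, X = X, y = y,
    table = table, excluded = exclude), class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Second-order model for", x$response,
      if (x$transform != "none") paste0("(", x$transform, ")"), "\n")
  cat(sprintf("R2 = %.3f  R2_pred = %.3f  df(total, model) = %d, %d\n",
              x$r_squared, x$r_squared_pred, x$df_total, x$df_model))
  tab <- data.frame(coef = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4), ...)
  invisible(x)
}

#' Hierarchy-respecting backward elimination
#'
#' Iteratively removes, one at a time, the term with the largest p-value
#' above `alpha`, refitting after each removal. A linear main effect is
#' never removed while a retained significant (p <= alpha) interaction or
#' quadratic term involves it, and the intercept is never removed. Stops
#' when no removable term exceeds `alpha`.
#'
#' @param fit an [fit_second_order()] result.
#' @param alpha significance level for retention (default 0.10).
#' @return A refitted `rsm_fit` on the reduced term set.
#' @export
backward_eliminate <- function(fit, alpha = 0.10) {
  repeat {
    terms <- fit$terms
    factor_names <- fit$ranges$name
    removable <- vapply(terms, function(tm) {
      if (tm == "intercept") return(FALSE)
      if (is_linear_term(tm, factor_names)) {
        children <- setdiff(terms[vapply(terms, function(o)
          tm %in% term_parents(o), logical(1))], tm)
        if (any(fit$p[children] <= alpha)) return(FALSE)
      }
      TRUE
    }, logical(1))
    cand <- terms[removable & fit$p > alpha]
    if (!length(cand)) return(fit)
    worst <- cand[which.max(fit$p[cand])]
    fit <- fit_second_order(fit$table, fit$response, fit$ranges,
                            fit$transform, setdiff(terms, worst),
                            fit$excluded)
  }
}

#' Predict mean response with its standard error
#'
#' Evaluates the fitted polynomial at new natural-unit conditions and
#' returns the standard error of the predicted mean response,
#' `s * sqrt(f' (X'X)^{-1} f)`. For a log10 fit, predictions can be
#' back-transformed (which keeps them strictly positive).
#'
#' @param fit an `rsm_fit`.
#' @param newdata data.frame or matrix of conditions in natural units.
#' @param back_transform undo a log10 response transform on the mean
#'   (the standard error stays on the modelling scale).
#' @return A list with `mean` and `se` vectors.
#' @export
predict_with_se <- function(fit, newdata, back_transform = FALSE) {
  coded <- to_coded(newdata, fit$ranges)
  f <- spec_model_matrix(coded, fit$terms, fit$ranges$name)
  mu <- drop(f %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((f %*% fit$XtXi) * f), 0) * fit$sigma2)
  if (back_transform && fit$transform == "log10") mu <- 10^mu
  list(mean = mu, se = se)
}

#' Flag outliers by externally studentized residuals
#'
#' @param fit an `rsm_fit`.
#' @param threshold flag rows whose `|externally studentized residual|`
#'   exceeds this (default 3).
#' @return Integer row indices of the original table that are flagged.
#' @export
flag_outliers <- function(fit, threshold = 3) {
  if (fit$df_residual - 1 < 1)
    stop("not enough residual degrees of freedom for studentization")
  # an exactly interpolating fit has no outliers (residuals are rounding
  # noise and studentization would divide rounding by rounding)
  if (fit$sigma2 <= 1e-10 * max(stats::var(fit$y), .Machine$double.xmin))
    return(integer(0))
  keep <- setdiff(seq_len(nrow(fit$table)), fit$excluded)
  keep[which(abs(fit$rstudent) > threshold)]
}

#' Export a fitted model summary
#'
#' Writes the coefficient table as CSV (`term, coefficient, se, t, p`) and
#' a JSON metrics block (R2, predictive R2, degrees of freedom, excluded
#' rows).
#'
#' @param fit an `rsm_fit`.
#' @param csv_path,json_path output file paths (either may be `NULL`).
#' @return The metrics list, invisibly.
#' @export
write_model_summary <- function(fit, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(term = fit$terms,
                                coefficient = fit$coefficients,
                                se = fit$se, t = fit$t, p = fit$p),
                     csv_path, row.names = FALSE)
  }
  metrics <- list(response = fit$response, transform = fit$transform,
                  r_squared = fit$r_squared,
                  r_squared_pred = fit$r_squared_pred,
                  df_total = fit$df_total, df_model = fit$df_model,
                  excluded_rows = fit$excluded)
  if (!is.null(json_path))
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
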