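test_that("noiseless quadratic data are recovered exactly", {
  beta <- c(50, -2, 1.5, 0.8, 0.5, -0.3, 0.2, -1.2, 0.7, -0.4)
  tab <- quadratic_table(beta)
  fit <- fit_second_order(tab, "yield", pilot_ranges())
  expect_equal(length(fit$coefficients), 10)  # 1 + 3 + 3 + 3 terms
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$df_total, 16)
  expect_equal(sum(fit$hat), 10, tolerance = 1e-8)
})

test_that("PRESS from the hat shortcut equals explicit leave-one-out refits", {
  beta <- c(50, -2, 1.5, 0.8, 0.5, -0.3, 0.2, -1.2, 0.7, -0.4)
  tab <- quadratic_table(beta, noise = 1.0, seed = 3)
  r <- pilot_ranges()
  fit <- fit_second_order(tab, "yield", r)

  # brute-force oracle: refit without each row, predict the held-out row
  coded <- to_coded(tab[, r$name], r)
  X <- spec_model_matrix_for_test(coded, r$name)
  y <- tab$yield
  press <- 0
  for (i in seq_len(nrow(X))) {
    b <- qr.solve(X[-i, ], y[-i])
    press <- press + (y[i] - drop(X[i, ] %*% b))^2
  }
  expect_equal(fit$press, press, tolerance = 1e-8)
  expect_equal(fit$r_squared_pred,
               1 - press / sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("backward elimination respects the term hierarchy", {
  r <- pilot_ranges()
  des <- ccf_design(3, 5, r)
  coded <- unclass(des)
  # strong pure-quadratic effect in factor 1, no linear effect
  set.seed(11)
  y <- 40 + 6 * coded[, 1]^2 + 3 * coded[, 2] + rnorm(nrow(coded), 0, 0.3)
  tab <- cbind(as.data.frame(to_natural(coded, r)), yield = y)
  fit <- fit_second_order(tab, "yield", r)
  red <- backward_eliminate(fit, alpha = 0.10)

  # the weak linear parent survives because its quadratic child is
  # significant; pure-noise terms are gone
  expect_true("temperature" %in% red$terms)
  expect_true("temperature^2" %in% red$terms)
  expect_true("time" %in% red$terms)
  expect_gt(fit$p["temperature"], 0.10)
  # no retained term outside the hierarchy protection is insignificant
  for (tm in setdiff(red$terms, c("intercept", r$name)))
    expect_lte(red$p[tm], 0.10)
  # hierarchy closure: every retained child has its parents retained
  for (tm in red$terms)
    expect_true(all(rsmbo:::term_parents(tm) %in% red$terms))
})

test_that("elimination leaves an all-significant model untouched and matches a manual refit", {
  r <- pilot_ranges()
  des <- ccf_design(3, 3, r)
  coded <- unclass(des)
  set.seed(5)
  y <- 40 + 5 * coded[, 1] - 3 * coded[, 2] + rnorm(nrow(coded), 0, 0.2)
  tab <- cbind(as.data.frame(to_natural(coded, r)), yield = y)
  terms0 <- c("intercept", "temperature", "time")
  fit <- fit_second_order(tab, "yield", r, terms = terms0)
  expect_identical(backward_eliminate(fit)$terms, terms0)

  # adding a pure-noise term and eliminating reproduces the small fit
  fit2 <- fit_second_order(tab, "yield", r,
                           terms = c(terms0, "ratio"))
  red <- backward_eliminate(fit2)
  expect_identical(red$terms, terms0)
  expect_equal(red$coefficients, fit$coefficients, tolerance = 1e-12)
})

test_that("prediction standard errors follow the design geometry", {
  r <- pilot_ranges()
  tab <- generate_table(make_pilot_truth(r), box_behnken(3, 3, r),
                        seed = 8)
  fit <- fit_second_order(tab, "yield", r)
  center <- matrix(c(140, 120, 7.5), 1)
  corner <- matrix(c(160, 180, 10), 1)
  p <- predict_with_se(fit, rbind(center, corner))
  expect_lt(p$se[1], p$se[2])

  # SE scales linearly with the residual standard deviation
  fit2 <- fit
  fit2$sigma2 <- 4 * fit$sigma2
  p2 <- predict_with_se(fit2, rbind(center, corner))
  expect_equal(p2$se, 2 * p$se, tolerance = 1e-12)

  # an exactly interpolating model reproduces training observations
  beta <- c(50, -2, 1.5, 0.8, 0.5, -0.3, 0.2, -1.2, 0.7, -0.4)
  tab0 <- quadratic_table(beta)
  fit0 <- fit_second_order(tab0, "yield", r)
  expect_equal(predict_with_se(fit0, tab0[, r$name])$mean, tab0$yield,
               tolerance = 1e-8)
})

test_that("log10 transform fits kappa-like responses and back-transforms positively", {
  r <- pilot_ranges()
  tab <- generate_table(make_pilot_truth(r), ccf_design(3, 3, r), seed = 2)
  fit <- fit_second_order(tab, "kappa", r, transform = "log10")
  grid <- expand.grid(temperature = c(120, 140, 160),
                      time = c(60, 120, 180), ratio = c(5, 10))
  pred <- predict_with_se(fit, grid, back_transform = TRUE)
  expect_true(all(pred$mean > 0))

  tab$kappa[1] <- -1
  expect_error(fit_second_order(tab, "kappa", r, transform = "log10"),
               "positive")
})

test_that("outlier flagging matches the external studentization formula", {
  beta <- c(50, -2, 1.5, 0.8, 0.5, -0.3, 0.2, -1.2, 0.7, -0.4)
  tab <- quadratic_table(beta, noise = 0.5, seed = 9)
  fit0 <- fit_second_order(tab, "yield", pilot_ranges())
  shift_row <- 6
  tab$yield[shift_row] <- tab$yield[shift_row] + 10 * sqrt(fit0$sigma2)
  fit <- fit_second_order(tab, "yield", pilot_ranges())
  expect_true(shift_row %in% flag_outliers(fit, 3))

  # manual formula oracle via lm() influence measures
  r <- pilot_ranges()
  coded <- as.data.frame(to_coded(tab[, r$name], r))
  names(coded) <- c("x1", "x2", "x3")
  lmfit <- lm(tab$yield ~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3 +
                I(x1^2) + I(x2^2) + I(x3^2), data = coded)
  expect_equal(unname(fit$rstudent), unname(rstudent(lmfit)),
               tolerance = 1e-8)

  # a perfect fit flags nothing, and flags ignore row order
  expect_length(flag_outliers(fit_second_order(quadratic_table(beta),
                                               "yield", r)), 0)
  perm <- sample(nrow(tab))
  fitp <- fit_second_order(tab[perm, ], "yield", r)
  expect_equal(sort(perm[flag_outliers(fitp, 3)]),
               sort(flag_outliers(fit, 3)))
})

test_that("model summaries export coefficients and metrics", {
  beta <- c(50, -2, 1.5, 0.8, 0.5, -0.3, 0.2, -1.2, 0.7, -0.4)
  tab <- quadratic_table(beta, noise = 0.5, seed = 4)
  fit <- fit_second_order(tab, "yield", pilot_ranges())
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_model_summary(fit, csv, js)
  co <- read.csv(csv)
  expect_equal(co$coefficient, unname(fit$coefficients), tolerance = 1e-12)
  met <- jsonlite::read_json(js)
  expect_equal(met$r_squared, fit$r_squared, tolerance = 1e-12)
  unlink(c(csv, js))
})
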