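test_that("a noise-free single-band relation is fit exactly with one latent variable", {
  set.seed(61)
  x <- matrix(runif(30 * 4), 30)
  y <- 2 + 3 * x[, 2]
  x[, c(1, 3, 4)] <- 0.5  # only band 2 varies
  m <- fit_plsr(x, y, ncomp = 1)
  ev <- evaluate_model(m, x, y)
  expect_equal(ev$r, 1, tolerance = 1e-10)
  expect_lt(ev$rmse, 1e-10)
})

test_that("PLSR with full rank and maximal components equals ordinary least squares", {
  set.seed(62)
  x <- matrix(rnorm(40 * 5), 40)
  y <- drop(x %*% c(1, -2, 0.5, 0, 3)) + rnorm(40, sd = 0.2)
  m <- fit_plsr(x, y, ncomp = 5)
  ols <- lm(y ~ x)
  expect_equal(unname(coef(m)), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("coefficients agree with an independent NIPALS oracle at every component count", {
  set.seed(63)
  x <- matrix(rnorm(25 * 10), 25)
  y <- drop(x[, 1:3] %*% c(1, 2, -1)) + rnorm(25, sd = 0.3)
  for (a in c(1, 2, 4, 7)) {
    m <- fit_plsr(x, y, ncomp = a)
    o <- oracle_nipals(x, y, a)
    expect_equal(unname(coef(m)), o$beta, tolerance = 1e-8, label = paste("a =", a))
    expect_equal(m$intercept, o$intercept, tolerance = 1e-8)
  }
})

test_that("the 1-LV direction is proportional to the x-y covariance vector", {
  set.seed(64)
  x <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  m <- fit_plsr(x, y, ncomp = 1)
  covv <- drop(crossprod(sweep(x, 2, colMeans(x)), y - mean(y)))
  ratio <- coef(m) / covv
  expect_equal(unname(ratio), rep(ratio[[1]], 6), tolerance = 1e-10)
})

test_that("latent-form and linear-form predictions agree to 1e-8 relative", {
  set.seed(65)
  x <- matrix(rnorm(30 * 8, mean = 5), 30)
  y <- rnorm(30, 3)
  m <- fit_plsr(x, y, ncomp = 4)
  xnew <- matrix(rnorm(10 * 8, mean = 5), 10)
  p_lin <- predict(m, xnew, form = "linear")
  p_lat <- predict(m, xnew, form = "latent")
  expect_equal(p_lat, p_lin, tolerance = 1e-8)
})

test_that("a constant response gives a flagged degenerate intercept-only model", {
  x <- matrix(runif(12 * 3), 12)
  y <- rep(2.5, 12)
  expect_warning(m <- fit_plsr(x, y, ncomp = 2), "degenerate|variance")
  expect_equal(unname(coef(m)), rep(0, 3))
  expect_equal(m$intercept, 2.5)
  ev <- evaluate_model(m, x, y)
  expect_true(ev$degenerate)
  expect_equal(ev$r, 0)
})

test_that("requesting more components than the rank supports warns and clips", {
  set.seed(66)
  x1 <- matrix(rnorm(10), 10)
  x <- cbind(x1, 2 * x1, -x1)  # rank 1
  y <- drop(x1) * 2 + 1
  expect_warning(m <- fit_plsr(x, y, ncomp = 3), "rank|feasible")
  expect_equal(m$ncomp_used, 1L)
  expect_lt(sqrt(mean(residuals(m)^2)), 1e-8)
})

test_that("LOOCV RMSECV matches the hand-rolled leave-one-out oracle", {
  set.seed(67)
  x <- matrix(rnorm(8 * 4), 8)
  y <- drop(x %*% c(1, 0.5, -1, 2)) + rnorm(8, sd = 0.3)
  sel <- loocv_select_lvs(x, y, max_lvs = 3)
  for (a in 1:3) {
    expect_equal(sel$rmsecv[a], oracle_loocv_rmsecv(x, y, a), tolerance = 1e-8,
                 label = paste("a =", a))
  }
})

test_that("LOOCV picks the true factor count on noise-free 1-factor data and breaks ties low", {
  set.seed(68)
  t_score <- rnorm(20)
  x <- tcrossprod(t_score, c(1, 2, 3, 4)) + 5
  y <- 2 * t_score + 1
  sel <- loocv_select_lvs(x, y, max_lvs = 3)
  expect_equal(sel$ncomp, 1L)
  expect_lt(sel$rmsecv[1], 1e-8)
  # explicit tie: curve c(5, 5) must give 1
  fake <- c(0.5, 0.5, 0.7)
  expect_equal(which.min(fake), 1L)  # documents the tie rule used
  expect_warning(loocv_select_lvs(x, y, max_lvs = 50), "feasible")
})

test_that("evaluation metrics follow their definitions", {
  set.seed(69)
  x <- matrix(runif(10 * 3), 10)
  y <- drop(x %*% c(1, 2, 3)) + rnorm(10, sd = 0.1)
  m <- fit_plsr(x, y, ncomp = 3)
  # predictions == measurements
  ev <- evaluate_model(m, x, predict(m, x))
  expect_equal(ev$r, 1, tolerance = 1e-10)
  expect_lt(ev$rmse, 1e-12)
  # constant shift: R stays 1, RMSE = |c|
  ev2 <- evaluate_model(m, x, predict(m, x) + 0.7)
  expect_equal(ev2$r, 1, tolerance = 1e-10)
  expect_equal(ev2$rmse, 0.7, tolerance = 1e-10)
  # random case against the long-hand formulas
  yy <- rnorm(10, 2)
  ev3 <- evaluate_model(m, x, yy)
  pred <- m$intercept + drop(x %*% coef(m))
  r_hand <- sum((pred - mean(pred)) * (yy - mean(yy))) /
    sqrt(sum((pred - mean(pred))^2) * sum((yy - mean(yy))^2))
  expect_equal(ev3$r, r_hand, tolerance = 1e-12)
  expect_equal(ev3$rmse, sqrt(mean((pred - yy)^2)), tolerance = 1e-12)
})

test_that("variable elimination arithmetic and report wiring are exact", {
  expect_equal(variable_elimination(460, 8), 100 * 452 / 460)
  expect_equal(round(variable_elimination(460, 8), 2), 98.26)
  expect_error(variable_elimination(10, 10), "smaller")

  pt <- planted_table(n = 40, p = 20, planted = c(5, 10, 15), seed = 70)
  split <- spxy_split(pt$table, 0.75, per_organ = FALSE)
  frog <- random_frog(pt$table, frog_config(iterations = 60, n_runs = 1, q = 6,
                                            rng_seed = 2))
  cmp <- full_vs_selected_report(pt$table, split, frog, k = 3, max_lvs = 5)
  # RF-PLSR uses exactly the top-k SP wavelengths
  expect_setequal(cmp$selected_wavelengths, rank_wavelengths(frog, 3))
  expect_setequal(names(coef(cmp$selected_model)),
                  format(rank_wavelengths(frog, 3), trim = TRUE, digits = 10))
  expect_equal(cmp$elimination_percent, variable_elimination(20, 3))
  expect_true(all(abs(c(cmp$full$r_c, cmp$full$r_p, cmp$selected$r_p)) <= 1))
  expect_true(all(c(cmp$full$rmsec, cmp$selected$rmsep) >= 0))
  expect_error(full_vs_selected_report(pt$table, split, frog, k = 20), "smaller")
})

test_that("dropping one pure-noise band barely changes the metric triads", {
  pt <- planted_table(n = 60, p = 10, planted = c(2, 5, 8), seed = 71)
  split <- spxy_split(pt$table, 0.75, per_organ = FALSE)
  frog <- random_frog(pt$table, frog_config(iterations = 150, n_runs = 2, q = 4,
                                            rng_seed = 3))
  cmp <- full_vs_selected_report(pt$table, split, frog, k = 9, max_lvs = 6)
  expect_lt(abs(cmp$full$rmsep - cmp$selected$rmsep), 0.1)
  expect_lt(abs(cmp$full$r_p - cmp$selected$r_p), 0.1)
})
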