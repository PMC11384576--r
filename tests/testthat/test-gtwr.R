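test_that("squared spacetime distance follows the additive combination", {
  p <- function(u, v, t) data.frame(u = u, v = v, t = t)
  expect_equal(st_distance_sq(p(1, 2, 2018), p(1, 2, 2018), 1, 1), 0)
  expect_equal(st_distance_sq(p(0, 0, 2018), p(3, 4, 2018), 1, 0), 25)
  expect_equal(st_distance_sq(p(0, 0, 2018), p(3, 4, 2020), 2, 1),
               2 * 25 + 1 * 4)
  expect_error(st_distance_sq(p(0, 0, 0), p(1, 1, 1), 0, 0), "lambda_s")
})

test_that("kernel weights match their closed forms", {
  expect_equal(kernel_weight(0, h = 2), 1)
  expect_equal(kernel_weight(4, h = 2), exp(-1))
  expect_equal(kernel_weight(100, h = 1e9), 1, tolerance = 1e-12)
  expect_equal(kernel_weight(c(0, 2, 4, 9), h = 2, family = "bisquare"),
               c(1, 0.25, 0, 0))
  expect_error(kernel_weight(1, h = 0), "positive")
  expect_error(kernel_weight(-1, h = 1), "nonnegative")
})

test_that("local WLS agrees with explicit normal equations", {
  # 3-observation instance, hand-checkable
  X <- cbind(1, c(0, 1, 2))
  y <- c(1, 3, 4)
  w <- c(1, 0.5, 0.25)
  expect_equal(unname(fit_local(X, y, w)), wls_oracle(X, y, w),
               tolerance = 1e-12)

  # identity weights reduce to OLS
  set.seed(31)
  X2 <- cbind(1, matrix(rnorm(40), 20, 2))
  y2 <- rnorm(20)
  expect_equal(unname(fit_local(X2, y2, rep(1, 20))),
               unname(coef(lm.fit(X2, y2))), tolerance = 1e-10)

  # exact linear data is reproduced under any positive weights
  y3 <- drop(X2 %*% c(2, -1, 0.5))
  b <- fit_local(X2, y3, runif(20, 0.1, 1))
  expect_equal(unname(b), c(2, -1, 0.5), tolerance = 1e-10)

  expect_error(fit_local(cbind(1, c(1, 1, 1)), c(1, 2, 3), c(1, 1, 1),
                         focal = 7),
               "singular.*7")
  expect_error(fit_local(X, y, c(1, 0, 0)), "too few")
})

test_that("local WLS matches the oracle on random instances to 1e-10", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    k <- sample(1:3, 1)
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    y <- rnorm(n)
    w <- runif(n, 0.05, 2)
    expect_equal(unname(fit_local(X, y, w)), wls_oracle(X, y, w),
                 tolerance = 1e-10)
  }
})

test_that("GTWR at huge bandwidth collapses to OLS", {
  gp <- make_stationary_panel(n_cities = 25, seed = 33)
  ols <- fit_ols(gp$panel)
  fit <- fit_gtwr(gp$panel, st_kernel_params(1e9, 1, 100))
  dev <- sweep(fit$coefficients, 2, ols$coefficients)
  expect_lt(max(abs(dev)), 1e-6)
  expect_lt(abs(fit$aicc - ols$aicc), 1e-3)
  expect_equal(fit$trace_s, length(ols$coefficients), tolerance = 1e-6)
})

test_that("zero-noise constant-coefficient panels are fit exactly", {
  gp <- make_linear_panel(n_cities = 15, seed = 34)
  for (h in c(20, 200, 1e6)) {
    fit <- fit_gtwr(gp$panel, st_kernel_params(h, 1, 50))
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("hat diagnostics satisfy their bounds", {
  gp <- make_stationary_panel(n_cities = 30, seed = 35)
  fit <- fit_gtwr(gp$panel, st_kernel_params(300, 1, 1000))
  p <- length(fit$covariates) + 1
  expect_true(all(fit$hat >= 0 & fit$hat <= 1))
  expect_gte(fit$trace_s, p - 1e-8)
  expect_lte(fit$trace_s, fit$n)
  expect_lte(fit$adj_r2, 1)
})

test_that("an overly small bandwidth raises the documented error", {
  panel <- data.frame(city_id = 1:30, u = seq_len(30), v = 0, t = 2018)
  set.seed(36)
  panel$X1 <- rnorm(30)
  panel$y <- 1 + panel$X1 + rnorm(30)
  expect_error(fit_gtwr(panel, st_kernel_params(0.3, 1, 0)),
               "bandwidth too small")
})

test_that("LOOCV equals brute-force refitting on a small panel", {
  gp <- make_stationary_panel(n_cities = 10, years = 2018:2019, seed = 37)
  panel <- gp$panel  # 20 observations
  params <- st_kernel_params(400, 1, 2000)

  cv <- loocv_score(panel, params)
  # oracle: refit on the 19 remaining rows, predict the held-out one
  d2 <- function(i, j) {
    (panel$u[i] - panel$u[j])^2 + (panel$v[i] - panel$v[j])^2 +
      2000 * (panel$t[i] - panel$t[j])^2
  }
  X <- cbind(1, panel$X1, panel$X2)
  brute <- 0
  for (i in seq_len(20)) {
    keep <- setdiff(seq_len(20), i)
    w <- exp(-sapply(keep, d2, i = i) / 400^2)
    beta <- wls_oracle(X[keep, ], panel$y[keep], w)
    brute <- brute + (panel$y[i] - sum(X[i, ] * beta))^2
  }
  expect_equal(cv, brute, tolerance = 1e-8)
})

test_that("LOOCV at huge bandwidth equals the OLS PRESS statistic", {
  gp <- make_stationary_panel(n_cities = 20, seed = 38)
  panel <- gp$panel
  X <- cbind(1, panel$X1, panel$X2)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  e <- panel$y - H %*% panel$y
  press <- sum((e / (1 - diag(H)))^2)
  cv <- loocv_score(panel, st_kernel_params(1e9, 1, 100))
  expect_equal(cv, press, tolerance = 1e-6 * press)
})

test_that("noiseless linear data gives a near-zero CV score", {
  gp <- make_linear_panel(n_cities = 12, seed = 39)
  expect_lt(loocv_score(gp$panel, st_kernel_params(100, 1, 50)), 1e-16)
})

test_that("bandwidth selection minimizes CV and prefers smoother models", {
  gp <- make_stationary_panel(n_cities = 30, seed = 40)
  grid <- c(100, 300, 1000, 3000)
  sel <- select_bandwidth(gp$panel, 1, 1000, grid = grid)
  expect_equal(sel$cv, min(sel$cv_curve$cv))
  expect_equal(sel$h_star, max(grid[sel$cv_curve$cv == sel$cv]))
  # stationary data favours global smoothing: CV decreases with h until the
  # flat-kernel plateau, so the selected bandwidth sits at the top of the grid
  expect_true(all(diff(sel$cv_curve$cv) <= 1e-8))
  expect_equal(sel$h_star, max(grid))
  # and the selected fit is already indistinguishable from OLS
  fit <- fit_gtwr(gp$panel, sel$params)
  ols <- fit_ols(gp$panel)
  expect_lt(max(abs(sweep(fit$coefficients, 2, ols$coefficients))), 0.05)
})

test_that("golden-section search agrees with a fine grid on unimodal CV", {
  gp <- make_recovery_panel(n_cities = 60, extent = 1000, seed = 41)
  mu <- (1000 / 6)^2
  gs <- select_bandwidth(gp$panel, 1, mu, lo = 50, hi = 1000, tol = 5)
  fine <- select_bandwidth(gp$panel, 1, mu,
                           grid = seq(50, 1000, by = 5))
  expect_lte(abs(gs$h_star - fine$h_star), 10)
})

test_that("OLS baseline matches closed forms and flags collinearity", {
  x <- seq_len(10)
  panel <- data.frame(city_id = 1:10, u = runif(10), v = runif(10), t = 2018,
                      y = 2 * x + 1, X1 = x)
  fit <- fit_ols(panel)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)

  set.seed(42)
  X <- cbind(1, rnorm(5))
  y <- rnorm(5)
  panel2 <- data.frame(city_id = 1:5, u = runif(5), v = runif(5), t = 2018,
                       y = y, X1 = X[, 2])
  fit2 <- fit_ols(panel2)
  expect_equal(unname(fit2$coefficients),
               drop(solve(crossprod(X), crossprod(X, y))), tolerance = 1e-10)
  expect_equal(unname(fit2$se),
               sqrt(diag(solve(crossprod(X))) *
                      sum((y - X %*% fit2$coefficients)^2) / (5 - 2)),
               tolerance = 1e-10)

  panel2$X2 <- panel2$X1
  expect_error(fit_ols(panel2), "collinear.*X")
})

test_that("default spacetime scales use the median nearest-neighbour spacing", {
  panel <- data.frame(city_id = 1:3, u = c(0, 1, 10), v = 0, t = 2018,
                      y = 1:3)
  sc <- st_scale_defaults(panel)
  # nearest-neighbour distances: 1, 1, 9 -> median 1
  expect_equal(sc$tau, 1)
  expect_equal(sc$mu_t, 1)
  expect_equal(sc$lambda_s, 1)
})
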