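test_that("spatial weight construction matches explicit adjacency oracles", {
  # 2 points, k = 1, standardized: both off-diagonal weights are 1
  W2 <- build_spatial_weights(data.frame(u = c(0, 1), v = 0), "knn", k = 1)
  expect_equal(unclass(W2), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  # rook contiguity on a 4x4 lattice via inverse distance at cutoff 1
  pts <- make_lattice_points(4)
  W <- build_spatial_weights(pts, "idw", cutoff = 1, row_standardize = FALSE)
  expect_equal(unclass(W), rook_adjacency(4), ignore_attr = TRUE)

  # row standardization: nonzero rows sum to one, diagonal stays zero
  Ws <- build_spatial_weights(pts, "knn", k = 3)
  expect_equal(unname(rowSums(Ws)), rep(1, 16))
  expect_equal(unname(diag(Ws)), rep(0, 16))

  expect_error(build_spatial_weights(pts, "knn", k = 16), "smaller")
  expect_error(build_spatial_weights(pts[1, ], "knn"), "at least 2")
  expect_error(build_spatial_weights(pts, "idw"), "cutoff")
})

test_that("Moran's I hits its closed forms", {
  pts <- make_lattice_points(4)
  W <- row_standardize(rook_adjacency(4))
  checker <- (-1)^(pts$u + pts$v)
  expect_equal(morans_i(checker, W), -1, tolerance = 1e-12)

  expect_error(morans_i(rep(3, 16), W), "constant")

  # cross-check against an independent implementation on random data
  skip_if_not_installed("ape")
  set.seed(50)
  x <- rnorm(16)
  expect_equal(morans_i(x, W),
               ape::Moran.I(x, W)$observed, tolerance = 1e-12)
})

test_that("the permutation null of Moran's I has mean -1/(n-1)", {
  pts <- make_lattice_points(4)
  W <- build_spatial_weights(pts, "knn", k = 4)
  set.seed(51)
  x <- rnorm(16)
  res <- morans_i_pvalue(x, W, n_perm = 4999, seed = 7)
  se <- sd(res$perm_i) / sqrt(res$n_perm)
  expect_lt(abs(mean(res$perm_i) - (-1 / 15)), 4 * se)
})

test_that("Moran's I lies within the symmetrized-weights eigenvalue bounds", {
  set.seed(52)
  pts <- data.frame(u = runif(12), v = runif(12))
  W <- build_spatial_weights(pts, "knn", k = 3)
  M <- (unclass(W) + t(unclass(W))) / 2
  ev <- eigen(M, only.values = TRUE)$values
  n <- 12; s0 <- sum(W)
  for (i in 1:5) {
    x <- rnorm(n)
    I <- morans_i(x, W)
    expect_gte(I, (n / s0) * min(ev) - 1e-10)
    expect_lte(I, (n / s0) * max(ev) + 1e-10)
  }
})

test_that("permutation p-values are deterministic and detect structure", {
  pts <- make_lattice_points(4)
  W <- row_standardize(rook_adjacency(4))
  checker <- (-1)^(pts$u + pts$v)
  res <- morans_i_pvalue(checker, W, n_perm = 999, seed = 3,
                         alternative = "two_sided")
  expect_equal(res$p_value, 1 / 1000)
  res2 <- morans_i_pvalue(checker, W, n_perm = 999, seed = 3,
                          alternative = "two_sided")
  expect_identical(res$p_value, res2$p_value)

  # smooth radial gradient: strong positive autocorrelation
  set.seed(53)
  pts2 <- data.frame(u = runif(60, 0, 100), v = runif(60, 0, 100))
  x <- exp(-sqrt((pts2$u - 50)^2 + (pts2$v - 50)^2) / 30) + rnorm(60, 0, 0.05)
  W2 <- build_spatial_weights(pts2, "knn", k = 5)
  expect_lte(morans_i_pvalue(x, W2, n_perm = 999, seed = 4,
                             alternative = "greater")$p_value, 0.001)
})

test_that("nonstationarity test compares the local IQR with twice the OLS SE", {
  coefs <- cbind("(Intercept)" = rep(0, 8), X1 = 1:8)
  fit <- fake_gtwr_fit(coefs)
  ols <- fake_ols_fit(c("(Intercept)" = 1, X1 = 1.6))
  out <- nonstationarity_test(fit, ols)
  # type-7 quantiles of 1..8: Q1 = 2.75, Q3 = 6.25
  expect_equal(out$iqr[out$variable == "X1"], 3.5)
  expect_equal(out$two_se, c(2, 3.2))
  expect_identical(out$nonstationary, c(FALSE, TRUE))
})

test_that("coefficient summaries use linear-interpolation quantiles", {
  fit <- fake_gtwr_fit(cbind("(Intercept)" = rep(2, 4), X1 = c(0, 1, 2, 3)))
  s <- summarize_coefficients(fit)
  x1 <- s[s$variable == "X1", ]
  expect_equal(unlist(x1[c("LQ", "MED", "UQ")], use.names = FALSE),
               c(0.75, 1.5, 2.25))
  ic <- s[s$variable == "(Intercept)", ]
  expect_true(all(unlist(ic[-1]) == 2))
  # ordering invariant on arbitrary fits
  set.seed(54)
  rnd <- fake_gtwr_fit(cbind(A = rnorm(20), B = rnorm(20)))
  sr <- summarize_coefficients(rnd)
  expect_true(all(sr$MIN <= sr$LQ & sr$LQ <= sr$MED &
                    sr$MED <= sr$UQ & sr$UQ <= sr$MAX))
  expect_true(all(sr$MIN <= sr$AVG & sr$AVG <= sr$MAX))
})

test_that("period averages split at the given year with exact change", {
  coefs <- cbind(X1 = c(1, 2, 3, 4))
  fit <- fake_gtwr_fit(coefs, t = c(2018, 2019, 2020, 2021))
  pa <- period_average_coefficients(fit, split_year = 2020)
  expect_equal(pa$before_mean, 1.5)
  expect_equal(pa$during_mean, 3.5)
  expect_identical(pa$change, pa$during_mean - pa$before_mean)

  same <- fake_gtwr_fit(cbind(X1 = rep(5, 4)), t = c(2018, 2019, 2020, 2021))
  expect_equal(period_average_coefficients(same)$change, 0)

  expect_error(period_average_coefficients(fit, split_year = 2030),
               "non-empty")
})

test_that("a planted pandemic step is recovered in the period averages", {
  g <- generate_city_grid(60, 1000, seed = 55)
  delta <- 0.6
  ss <- surface_set(surface_constant(1),
                    list(X1 = surface_step(0.5, delta, 2020)),
                    noise_sd = 0.1)
  gp <- generate_panel(g, 2018:2021, ss, recovery_covariate_specs(1),
                       seed = 56)
  sel <- select_bandwidth(gp$panel, 1, (1000 / 6)^2,
                          grid = c(100, 200, 400, 800))
  fit <- fit_gtwr(gp$panel, sel$params)
  pa <- period_average_coefficients(fit, split_year = 2020)
  est <- pa$change[pa$variable == "X1"]
  expect_lt(abs(est - delta), 0.25 * delta)
})

test_that("the assembled diagnostics report has every section", {
  gp <- make_recovery_panel(n_cities = 40, extent = 1000, seed = 57)
  sel <- select_bandwidth(gp$panel, 1, (1000 / 6)^2, grid = c(200, 500))
  fit <- fit_gtwr(gp$panel, sel$params)
  ols <- fit_ols(gp$panel)
  rep <- diagnostics_report(gp$panel, fit, ols, n_perm = 199, seed = 5)
  expect_named(rep, c("morans_i", "nonstationarity", "coefficient_summary",
                      "period_averages", "model_comparison"))
  expect_named(rep$coefficient_summary,
               c("variable", "AVG", "MIN", "LQ", "MED", "UQ", "MAX"))
  expect_named(rep$period_averages,
               c("variable", "before_mean", "during_mean", "change"))
  rep2 <- diagnostics_report(gp$panel, fit, ols, n_perm = 199, seed = 5)
  expect_identical(rep$morans_i$p_value, rep2$morans_i$p_value)
})
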