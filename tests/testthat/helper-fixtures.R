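# Shared fixtures: small panels with known structure and independent oracles.

# Explicit weighted-normal-equations solve; intentionally naive and
# independent of the package's QR path.
wls_oracle <- function(X, y, w) {
  W <- diag(w, nrow = length(w))
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# Panel with exactly linear response (zero noise, constant coefficients).
make_linear_panel <- function(n_cities = 20, years = 2018:2019,
                              beta = c(1, 2, -0.5), seed = 5) {
  g <- generate_city_grid(n_cities, 100, seed = seed)
  ss <- surface_set(
    intercept = surface_constant(beta[1]),
    beta = list(X1 = surface_constant(beta[2]),
                X2 = surface_constant(beta[3])),
    noise_sd = 0
  )
  generate_panel(g, years, ss, recovery_covariate_specs(2), seed = seed + 1)
}

# Noisy but stationary (constant-coefficient) panel.
make_stationary_panel <- function(n_cities = 40, years = 2018:2021,
                                  noise_sd = 0.3, seed = 9) {
  g <- generate_city_grid(n_cities, 1000, seed = seed)
  ss <- surface_set(
    intercept = surface_constant(1),
    beta = list(X1 = surface_constant(0.8), X2 = surface_constant(-0.4)),
    noise_sd = noise_sd
  )
  generate_panel(g, years, ss, recovery_covariate_specs(2), seed = seed + 1)
}

# Strongly nonstationary panel built from the recovery validation surfaces.
make_recovery_panel <- function(n_cities = 323, extent = 3000,
                                years = 2018:2021, noise_sd = 0.5,
                                seed = 11) {
  g <- generate_city_grid(n_cities, extent, seed = seed)
  cap <- which(g$city_id == attr(g, "capital_id"))
  ss <- recovery_surface_set(extent, c(g$u[cap], g$v[cap]),
                             noise_sd = noise_sd)
  generate_panel(g, years, ss, recovery_covariate_specs(3), seed = seed + 1)
}

# Square lattice coordinates (unit spacing), row-major.
make_lattice_points <- function(m) {
  expand.grid(u = seq_len(m) - 1, v = seq_len(m) - 1)
}

# Hand-built rook-contiguity adjacency on an m x m lattice.
rook_adjacency <- function(m) {
  n <- m * m
  A <- matrix(0, n, n)
  idx <- function(i, j) (j - 1) * m + i  # matches expand.grid order
  for (j in seq_len(m)) {
    for (i in seq_len(m)) {
      if (i < m) A[idx(i, j), idx(i + 1, j)] <- A[idx(i + 1, j), idx(i, j)] <- 1
      if (j < m) A[idx(i, j), idx(i, j + 1)] <- A[idx(i, j + 1), idx(i, j)] <- 1
    }
  }
  A
}

row_standardize <- function(A) {
  rs <- rowSums(A)
  A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  A
}

# A gtwr_fit-shaped object with planted local coefficients, for testing the
# diagnostics arithmetic in isolation from the estimator.
fake_gtwr_fit <- function(coefs, t = rep(2018, nrow(coefs))) {
  structure(
    list(coefficients = coefs, n = nrow(coefs),
         obs = data.frame(city_id = seq_len(nrow(coefs)),
                          u = 0, v = 0, t = t)),
    class = "gtwr_fit"
  )
}

fake_ols_fit <- function(se) {
  structure(list(coefficients = setNames(numeric(length(se)), names(se)),
                 se = se),
            class = "ols_fit")
}
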