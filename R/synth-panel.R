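#' Covariate specification
#'
#' Describes the marginal distribution a synthetic covariate is drawn from:
#' a normal distribution truncated to `[min, max]`, or a Bernoulli for binary
#' indicators such as administrative city type.
#'
#' @param name Covariate name (unique within a panel).
#' @param family `"truncnorm"` or `"bernoulli"`.
#' @param mean,sd,min,max Moments and truncation bounds (truncnorm only).
#' @param prob Success probability (bernoulli only).
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, family = c("truncnorm", "bernoulli"),
                           mean = NULL, sd = NULL, min = NULL, max = NULL,
                           prob = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (family == "truncnorm") {
    stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(min), is.numeric(max))
    if (!(min <= mean && mean <= max)) {
      stop(sprintf("covariate '%s': need min <= mean <= max", name),
           call. = FALSE)
    }
    if (sd <= 0) stop(sprintf("covariate '%s': sd must be > 0", name),
                      call. = FALSE)
  } else {
    stopifnot(is.numeric(prob), length(prob) == 1L, prob >= 0, prob <= 1)
    mean <- prob; sd <- sqrt(prob * (1 - prob)); min <- 0; max <- 1
  }
  structure(list(name = name, family = family, mean = mean, sd = sd,
                 min = min, max = max, prob = prob),
            class = "covariate_spec")
}

# Published summary moments of the study variables (dependent HPA plus nine
# covariates) and the GTWR coefficient averages used to calibrate the default
# synthetic study emulation.
hpa_study_constants <- function() {
  list(
    hpa = c(mean = 1.3089, max = 2.5450, min = 0.3906, sd = 0.2690),
    hpa_before = 1.221, hpa_during = 1.366,
    covariates = list(
      PA     = c(mean = 0.9092,  max = 4.9465,   min = 0.0110,  sd = 0.7022),
      PGA    = c(mean = 1.3136,  max = 2.0010,   min = 0.7740,  sd = 0.2499),
      AGE65  = c(mean = 13.3916, max = 23.5260,  min = 2.9340,  sd = 3.4073),
      POP    = c(mean = 4.2903,  max = 32.1243,  min = 0.2038,  sd = 3.6394),
      UR     = c(mean = 59.6278, max = 99.7500,  min = 21.8700, sd = 13.7270),
      GDPPER = c(mean = 6.3309,  max = 21.8118,  min = 1.2447,  sd = 3.4921),
      BEPER  = c(mean = 1.3172,  max = 2.5450,   min = 0.3906,  sd = 0.6893),
      AQI    = c(mean = 66.7891, max = 126.6078, min = 23.1096, sd = 18.9123)
    ),
    ct_prob = 0.8869,
    # period-mean coefficients (before 2020) and their pandemic-step changes
    beta_before = c(PA = 0.0002, PGA = 0.1896, AGE65 = -0.0035, POP = 0.0038,
                    UR = -0.0011, GDPPER = -0.0081, BEPER = 0.0144,
                    CT = 0.0232, AQI = -0.0025),
    beta_change = c(PA = 0.0006, PGA = 0.0273, AGE65 = 0.0004, POP = -0.0047,
                    UR = 0.0010, GDPPER = -0.0029, BEPER = 0.0082,
                    CT = -0.0845, AQI = 0.0014)
  )
}

#' Default covariate specifications
#'
#' The nine study covariates — public attention (PA), provincial government
#' attention (PGA), population share aged 65+ (AGE65), population (POP),
#' urbanisation rate (UR), GDP per capita (GDPPER), per-capita budget
#' expenditure (BEPER), administrative city type (CT, binary) and air quality
#' index (AQI) — with truncated-normal (or Bernoulli for CT) marginals whose
#' means, SDs and ranges match the published variable summary.
#'
#' @return A list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  k <- hpa_study_constants()
  specs <- lapply(names(k$covariates), function(nm) {
    m <- k$covariates[[nm]]
    covariate_spec(nm, "truncnorm", mean = m[["mean"]], sd = m[["sd"]],
                   min = m[["min"]], max = m[["max"]])
  })
  specs <- append(specs, list(covariate_spec("CT", "bernoulli",
                                             prob = k$ct_prob)), after = 7)
  specs
}

#' Default study-emulation coefficient surfaces
#'
#' Coefficient surfaces calibrated to the published GTWR summary: each
#' covariate's surface is its pre-pandemic period-mean coefficient plus a
#' step change at `t >= 2020` equal to the published period difference; PGA
#' and BEPER additionally carry a smooth east-west gradient spanning roughly
#' the published lower-to-upper-quartile spread; the intercept carries an
#' east-west gradient plus a pandemic step sized so the panel reproduces the
#' published HPA period means (1.221 before, 1.366 during). `noise_sd`
#' (default 0.22) is set so the marginal HPA standard deviation comes out
#' near the published 0.269.
#'
#' @param extent_km Side length of the city grid the panel will live on.
#' @param noise_sd Residual standard deviation on the HPA percent scale.
#' @return A [surface_set()].
#' @export
study_surface_set <- function(extent_km, noise_sd = 0.22) {
  check_positive_scalar(extent_km, "extent_km")
  k <- hpa_study_constants()
  means <- c(vapply(k$covariates, `[[`, numeric(1), "mean"), CT = k$ct_prob)
  nm <- names(k$beta_before)

  beta <- lapply(nm, function(x) {
    s <- surface_step(k$beta_before[[x]], k$beta_change[[x]], year = 2020)
    grad <- switch(x, PGA = 0.12, BEPER = 0.024, 0)
    if (grad != 0) {
      s <- surface_sum(s, surface_linear(grad / 2, du = -grad / extent_km))
    }
    s
  })
  names(beta) <- nm

  # intercept calibrated so period means of y match the published HPA means
  b00 <- k$hpa_before - sum(k$beta_before * means[nm])
  delta0 <- (k$hpa_during - k$hpa_before) - sum(k$beta_change * means[nm])
  intercept <- surface_sum(
    surface_step(b00, delta0, year = 2020),
    surface_linear(0.2, du = -0.4 / extent_km)
  )
  surface_set(intercept, beta, noise_sd = noise_sd)
}

#' Parameter-recovery validation surfaces
#'
#' A deliberately strong, smooth nonstationary scenario used to validate the
#' GTWR engine: three standardized covariates whose coefficients vary as an
#' east-west gradient, a radial decay from the capital, and a pandemic step,
#' over an intercept with a north-south gradient. Surface variation is large
#' relative to `noise_sd` (default 0.5) so local estimates are expected to
#' track the true surfaces closely.
#'
#' @param extent_km Side length of the city grid.
#' @param capital_uv Length-2 vector with the capital's (u, v), km.
#' @param noise_sd Residual standard deviation.
#' @return A [surface_set()] with covariates `X1`, `X2`, `X3`.
#' @export
recovery_surface_set <- function(extent_km, capital_uv, noise_sd = 0.5) {
  check_positive_scalar(extent_km, "extent_km")
  surface_set(
    intercept = surface_linear(1, dv = 1 / extent_km),
    beta = list(
      X1 = surface_linear(1, du = 1 / extent_km),
      X2 = surface_radial(1.5, range_km = 0.3 * extent_km,
                          centre = capital_uv),
      X3 = surface_step(0.5, 0.5, year = 2020)
    ),
    noise_sd = noise_sd
  )
}

#' Standardized covariate specs for the recovery scenario
#'
#' @param k Number of covariates (named `X1..Xk`), each standard normal
#'   truncated to `[-3, 3]`.
#' @return A list of [covariate_spec()] objects.
#' @export
recovery_covariate_specs <- function(k = 3) {
  lapply(seq_len(k), function(i) {
    covariate_spec(paste0("X", i), "truncnorm", mean = 0, sd = 1,
                   min = -3, max = 3)
  })
}

#' Generate a synthetic city-by-year panel with known coefficient truth
#'
#' Draws covariates per their specifications, evaluates the coefficient
#' surfaces at every (city, year), and builds the dependent variable from the
#' varying-coefficient model
#' \deqn{y_i = \beta_0(u_i, v_i, t_i) + \sum_k \beta_k(u_i, v_i, t_i) x_{ik}
#'   + \varepsilon_i, \quad \varepsilon_i \sim N(0, \sigma^2).}
#' The true coefficient matrix is returned row-aligned with the panel so
#' estimator recovery can be measured exactly.
#'
#' @param grid A [generate_city_grid()] result (or data frame with `city_id`,
#'   `u`, `v`).
#' @param years Integer vector of panel years (non-empty).
#' @param surfaces A [surface_set()] whose `beta` names match the covariate
#'   names.
#' @param covariates List of [covariate_spec()] objects with unique names.
#' @param seed Integer seed (bit-reproducible output).
#'
#' @return A list with `panel` (data.frame: `city_id`, `u`, `v`, `t`, `y`,
#'   covariate columns) and `truth` (numeric matrix, one row per panel row,
#'   columns `(Intercept)` then the covariates).
#' @export
generate_panel <- function(grid, years, surfaces, covariates, seed) {
  stopifnot(is.data.frame(grid),
            all(c("city_id", "u", "v") %in% names(grid)))
  if (length(years) == 0) stop("`years` must be non-empty", call. = FALSE)
  if (!inherits(surfaces, "surface_set")) {
    stop("`surfaces` must be a surface_set", call. = FALSE)
  }
  cov_names <- vapply(covariates, function(s) s$name, character(1))
  if (anyDuplicated(cov_names)) {
    stop("covariate names must be unique", call. = FALSE)
  }
  if (!setequal(names(surfaces$beta), cov_names)) {
    stop("surface set names must match covariate names; missing: ",
         paste(setdiff(cov_names, names(surfaces$beta)), collapse = ", "),
         call. = FALSE)
  }

  years <- sort(as.integer(years))
  n_city <- nrow(grid)
  n <- n_city * length(years)
  panel <- data.frame(
    city_id = rep(grid$city_id, times = length(years)),
    u = rep(grid$u, times = length(years)),
    v = rep(grid$v, times = length(years)),
    t = rep(years, each = n_city)
  )

  eval_surface <- function(f, label) {
    val <- f(panel$u, panel$v, panel$t)
    if (length(val) != n || !all(is.finite(val))) {
      stop(sprintf("surface '%s' is not evaluable over the grid", label),
           call. = FALSE)
    }
    val
  }

  truth <- matrix(NA_real_, n, length(cov_names) + 1L,
                  dimnames = list(NULL, c("(Intercept)", cov_names)))
  truth[, 1L] <- eval_surface(surfaces$intercept, "(Intercept)")
  for (nm in cov_names) {
    truth[, nm] <- eval_surface(surfaces$beta[[nm]], nm)
  }

  with_seed(seed, {
    for (spec in covariates) {
      panel[[spec$name]] <- if (spec$family == "bernoulli") {
        rbinom(n, 1L, spec$prob)
      } else {
        rtruncnorm(n, spec$mean, spec$sd, spec$min, spec$max)
      }
    }
    x <- as.matrix(panel[, cov_names, drop = FALSE])
    eps <- if (surfaces$noise_sd > 0) rnorm(n, 0, surfaces$noise_sd) else 0
    panel$y <- truth[, 1L] + rowSums(truth[, cov_names, drop = FALSE] * x) + eps
  })

  panel <- panel[, c("city_id", "u", "v", "t", "y", cov_names)]
  list(panel = panel, truth = truth)
}
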