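# Geographically and temporally weighted regression: spacetime kernel
# weights, local weighted least squares, leave-one-out CV bandwidth
# selection, and the OLS baseline.

#' Spacetime kernel parameters
#'
#' @param h Bandwidth (> 0) applied to the combined spacetime distance.
#' @param lambda_s Spatial scale weight (>= 0).
#' @param mu_t Temporal scale weight (>= 0); `lambda_s + mu_t` must be
#'   positive.
#' @param family Kernel family, `"gaussian"` (default) or `"bisquare"`.
#' @return An object of class `st_kernel_params`.
#' @export
st_kernel_params <- function(h, lambda_s = 1, mu_t = 0,
                             family = c("gaussian", "bisquare")) {
  family <- match.arg(family)
  check_positive_scalar(h, "h")
  if (lambda_s < 0 || mu_t < 0 || lambda_s + mu_t <= 0) {
    stop("need lambda_s >= 0, mu_t >= 0 and lambda_s + mu_t > 0",
         call. = FALSE)
  }
  structure(list(h = h, lambda_s = lambda_s, mu_t = mu_t, family = family),
            class = "st_kernel_params")
}

#' Squared spacetime distance between two observations
#'
#' Additive combination of squared spatial and temporal separation:
#' \deqn{d^2_{ST} = \lambda_s [(u_i - u_j)^2 + (v_i - v_j)^2] +
#'   \mu_t (t_i - t_j)^2.}
#'
#' @param i,j Observation points: named vectors, lists or one-row data frames
#'   with `u`, `v`, `t`.
#' @param lambda_s,mu_t Nonnegative scale weights, not both zero.
#' @return Squared distance (>= 0).
#' @export
st_distance_sq <- function(i, j, lambda_s = 1, mu_t = 0) {
  if (lambda_s < 0 || mu_t < 0 || lambda_s + mu_t <= 0) {
    stop("need lambda_s >= 0, mu_t >= 0 and lambda_s + mu_t > 0",
         call. = FALSE)
  }
  gi <- function(p, f) as.numeric(if (is.data.frame(p)) p[[f]][1] else p[[f]])
  lambda_s * ((gi(i, "u") - gi(j, "u"))^2 + (gi(i, "v") - gi(j, "v"))^2) +
    mu_t * (gi(i, "t") - gi(j, "t"))^2
}

#' Kernel weight from a squared distance
#'
#' Gaussian: `exp(-d2 / h^2)`; bisquare: `(1 - d2 / h^2)^2` inside the
#' bandwidth, 0 beyond it.
#'
#' @param d2 Squared spacetime distance(s), >= 0.
#' @param h Bandwidth (> 0).
#' @param family `"gaussian"` or `"bisquare"`.
#' @return Weights in `[0, 1]` (strictly positive for gaussian).
#' @export
kernel_weight <- function(d2, h, family = c("gaussian", "bisquare")) {
  family <- match.arg(family)
  check_positive_scalar(h, "h")
  if (any(d2 < 0)) stop("`d2` must be nonnegative", call. = FALSE)
  r <- d2 / h^2
  if (family == "gaussian") exp(-r) else ifelse(r < 1, (1 - r)^2, 0)
}

# ---- internal fitting machinery ------------------------------------------

# Relative QR tolerance below which a weighted design is declared singular.
WLS_RANK_TOL <- 1e-10

# Weighted least squares through a pivoted QR of the sqrt(w)-scaled system.
# Returns the coefficient vector plus the pieces needed for hat diagonals.
wls_qr <- function(X, y, w, context = NULL) {
  keep <- w > 0
  if (sum(keep) < ncol(X)) {
    stop(sprintf("too few positively weighted observations (%d < %d)%s",
                 sum(keep), ncol(X),
                 if (is.null(context)) "" else paste0(" ", context)),
         call. = FALSE)
  }
  sw <- sqrt(w)
  qrx <- qr(X * sw, tol = WLS_RANK_TOL)
  if (qrx$rank < ncol(X)) {
    stop(sprintf("singular weighted design%s",
                 if (is.null(context)) "" else paste0(" ", context)),
         call. = FALSE)
  }
  beta <- qr.coef(qrx, y * sw)
  list(beta = beta, qr = qrx)
}

# x' (X'WX)^{-1} x for one focal row, from the pivoted QR factor.
quad_form_inv <- function(qrx, x) {
  R <- qr.R(qrx)
  z <- backsolve(R, x[qrx$pivot], transpose = TRUE)
  sum(z^2)
}

build_design <- function(panel, covariates = NULL) {
  stopifnot(is.data.frame(panel),
            all(c("city_id", "u", "v", "t", "y") %in% names(panel)))
  if (is.null(covariates)) {
    covariates <- setdiff(names(panel), c("city_id", "u", "v", "t", "y"))
  }
  missing <- setdiff(covariates, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(panel$city_id, panel$t))) {
    stop("(city_id, t) keys must be unique", call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1,
             as.matrix(panel[, covariates, drop = FALSE]))
  if (!all(is.finite(X)) || !all(is.finite(panel$y))) {
    stop("panel contains non-finite values", call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("panel needs more observations than parameters", call. = FALSE)
  }
  list(X = X, y = panel$y, covariates = covariates)
}

# Full n x n squared spacetime distance matrix (years centred first).
st_dist2_matrix <- function(panel, lambda_s, mu_t) {
  du <- outer(panel$u, panel$u, "-")
  dv <- outer(panel$v, panel$v, "-")
  tc <- panel$t - mean(panel$t)
  dt <- outer(tc, tc, "-")
  lambda_s * (du^2 + dv^2) + mu_t * dt^2
}

# GWR-convention corrected AIC with trace(S) effective parameters.
aicc_gwr <- function(rss, n, trace_s) {
  sigma_hat <- sqrt(rss / n)
  2 * n * log(sigma_hat) + n * log(2 * pi) +
    n * (n + trace_s) / (n - 2 - trace_s)
}

# ---- exported fitting functions ------------------------------------------

#' Local weighted least squares
#'
#' Solves \eqn{(X^T W X)\beta = X^T W y} with `W = diag(w)` through a
#' numerically stable QR factorization of the `sqrt(w)`-scaled system.
#'
#' @param X Design matrix including the intercept column.
#' @param y Response vector.
#' @param w Nonnegative weights; at least `ncol(X)` must be positive.
#' @param focal Optional label (e.g. observation index) included in
#'   singularity error messages.
#' @return Named coefficient vector.
#' @export
fit_local <- function(X, y, w, focal = NULL) {
  X <- as.matrix(X)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  ctx <- if (is.null(focal)) NULL else sprintf("at focal observation %s", focal)
  wls_qr(X, y, w, context = ctx)$beta
}

#' Fit a geographically and temporally weighted regression
#'
#' At every observation `i`, kernel weights are computed from the squared
#' spacetime distances to all observations and a local weighted least squares
#' fit produces the coefficient vector \eqn{\beta(u_i, v_i, t_i)}. Fit
#' statistics follow the GWR conventions: the hat diagonal is
#' \eqn{s_{ii} = x_i^T (X^T W_i X)^{-1} X^T W_i e_i}, `trace_S` is the sum of
#' hat diagonals (effective number of parameters), AICc is
#' \eqn{2n\log\hat\sigma + n\log 2\pi + n(n + tr S)/(n - 2 - tr S)} with
#' \eqn{\hat\sigma^2 = RSS/n}, and adjusted \eqn{R^2} uses `trace_S` in place
#' of the parameter count.
#'
#' @param panel Panel data frame with columns `city_id`, `u`, `v`, `t`, `y`
#'   and the covariates; `(city_id, t)` unique.
#' @param params [st_kernel_params()].
#' @param covariates Covariate column names; default: every column other than
#'   `city_id`, `u`, `v`, `t`, `y`.
#' @return An object of class `gtwr_fit`: local coefficient matrix
#'   (`n x (k+1)`), fitted values, residuals, hat diagonal, `trace_S`,
#'   `sigma2`, `aicc`, `adj_r2`, the kernel parameters and the observation
#'   frame.
#' @export
fit_gtwr <- function(panel, params, covariates = NULL) {
  stopifnot(inherits(params, "st_kernel_params"))
  d <- build_design(panel, covariates)
  X <- d$X; y <- d$y
  n <- nrow(X); p <- ncol(X)

  d2 <- st_dist2_matrix(panel, params$lambda_s, params$mu_t)
  coefs <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  hat <- numeric(n)
  fitted <- numeric(n)

  for (i in seq_len(n)) {
    w <- kernel_weight(d2[, i], params$h, params$family)
    fit <- tryCatch(
      wls_qr(X, y, w, context = sprintf(
        "at focal observation %d (city %s, t %s)",
        i, panel$city_id[i], panel$t[i])),
      error = function(e) stop(e)
    )
    coefs[i, ] <- fit$beta
    fitted[i] <- sum(X[i, ] * fit$beta)
    hat[i] <- w[i] * quad_form_inv(fit$qr, X[i, ])
  }

  resid <- y - fitted
  trace_s <- sum(hat)
  if (trace_s >= n - 2) {
    stop(sprintf(paste0("bandwidth too small: effective parameters ",
                        "trace(S) = %.2f >= n - 2 = %d"), trace_s, n - 2),
         call. = FALSE)
  }
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / (n - trace_s)) / (tss / (n - 1))

  structure(
    list(
      coefficients = coefs,
      fitted = fitted,
      residuals = resid,
      hat = hat,
      trace_s = trace_s,
      sigma2 = rss / n,
      aicc = aicc_gwr(rss, n, trace_s),
      adj_r2 = adj_r2,
      params = params,
      covariates = d$covariates,
      obs = panel[, c("city_id", "u", "v", "t")],
      n = n
    ),
    class = "gtwr_fit"
  )
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf(paste0("GTWR fit: n = %d, %d covariates, h = %g ",
                     "(lambda_s = %g, mu_t = %g, %s kernel)\n"),
              x$n, length(x$covariates), x$params$h, x$params$lambda_s,
              x$params$mu_t, x$params$family))
  cat(sprintf("  trace(S) = %.2f, AICc = %.3f, adjusted R^2 = %.4f\n",
              x$trace_s, x$aicc, x$adj_r2))
  invisible(x)
}

#' Leave-one-out cross-validation score
#'
#' For each observation, the local fit is recomputed with the focal
#' observation's own weight forced to zero and the focal response predicted;
#' the score is the sum of squared prediction errors. A singular focal fit
#' yields an infinite score (with a warning) so bandwidth search can step
#' over it.
#'
#' @inheritParams fit_gtwr
#' @return The CV score (>= 0), possibly `Inf`.
#' @export
loocv_score <- function(panel, params, covariates = NULL) {
  stopifnot(inherits(params, "st_kernel_params"))
  d <- build_design(panel, covariates)
  X <- d$X; y <- d$y
  n <- nrow(X)
  d2 <- st_dist2_matrix(panel, params$lambda_s, params$mu_t)

  err2 <- 0
  for (i in seq_len(n)) {
    w <- kernel_weight(d2[, i], params$h, params$family)
    w[i] <- 0
    beta <- tryCatch(wls_qr(X, y, w)$beta, error = function(e) NULL)
    if (is.null(beta)) {
      warning(sprintf(paste0("singular leave-one-out fit at observation %d; ",
                             "CV score set to Inf"), i), call. = FALSE)
      return(Inf)
    }
    err2 <- err2 + (y[i] - sum(X[i, ] * beta))^2
  }
  err2
}

#' Select the bandwidth by leave-one-out cross-validation
#'
#' Minimizes [loocv_score()] over a bandwidth grid or by golden-section
#' search on `[lo, hi]` (the CV curve is typically unimodal in `h`). Ties are
#' broken toward the larger bandwidth, i.e. the smoother and better
#' conditioned model.
#'
#' @inheritParams fit_gtwr
#' @param lambda_s,mu_t Spacetime scale weights (see [st_kernel_params()]).
#' @param grid Optional increasing vector of candidate bandwidths.
#' @param lo,hi Golden-section bracket (used when `grid` is `NULL`).
#' @param tol Absolute golden-section tolerance on `h`; default
#'   `(hi - lo) * 1e-3`.
#' @param family Kernel family.
#' @return A list: `h_star`, `cv` (score at `h_star`), `cv_curve` (data.frame
#'   of every evaluated `h` and score), and `params` ready for [fit_gtwr()].
#' @export
select_bandwidth <- function(panel, lambda_s = 1, mu_t = 0, grid = NULL,
                             lo = NULL, hi = NULL, tol = NULL,
                             family = "gaussian", covariates = NULL) {
  evals_h <- numeric(0)
  evals_cv <- numeric(0)
  score <- function(h) {
    cv <- loocv_score(panel,
                      st_kernel_params(h, lambda_s, mu_t, family = family),
                      covariates)
    evals_h <<- c(evals_h, h)
    evals_cv <<- c(evals_cv, cv)
    cv
  }

  if (!is.null(grid)) {
    if (length(grid) == 0) stop("`grid` must be non-empty", call. = FALSE)
    grid <- sort(grid)
    for (h in grid) score(h)
    best <- min(evals_cv)
    if (!is.finite(best)) {
      stop("no valid bandwidth: every candidate gave an infinite CV score",
           call. = FALSE)
    }
    h_star <- max(evals_h[evals_cv == best])
  } else {
    if (is.null(lo) || is.null(hi) || !(lo < hi) || lo <= 0) {
      stop("golden-section search needs 0 < lo < hi", call. = FALSE)
    }
    if (is.null(tol)) tol <- (hi - lo) * 1e-3
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- score(x1); f2 <- score(x2)
    while (b - a > tol) {
      if (f1 > f2 || (f1 == f2)) {  # ties move toward larger h
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- score(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- score(x1)
      }
    }
    finite <- is.finite(evals_cv)
    if (!any(finite)) {
      stop("no valid bandwidth: every evaluation gave an infinite CV score",
           call. = FALSE)
    }
    best <- min(evals_cv[finite])
    h_star <- max(evals_h[finite][evals_cv[finite] == best])
  }

  ord <- order(evals_h)
  list(
    h_star = h_star,
    cv = min(evals_cv[is.finite(evals_cv)]),
    cv_curve = data.frame(h = evals_h[ord], cv = evals_cv[ord]),
    params = st_kernel_params(h_star, lambda_s, mu_t, family = family)
  )
}

#' Ordinary least squares baseline
#'
#' Classical OLS on the same design, with coefficient standard errors (used
#' by the nonstationarity test), the GWR-convention AICc evaluated at
#' `trace_S = k + 1`, and adjusted R-squared.
#'
#' @inheritParams fit_gtwr
#' @return An object of class `ols_fit`: `coefficients`, `se`, `residuals`,
#'   `fitted`, `aicc`, `adj_r2`, `sigma2`, `covariates`, `n`.
#' @export
fit_ols <- function(panel, covariates = NULL) {
  d <- build_design(panel, covariates)
  X <- d$X; y <- d$y
  n <- nrow(X); p <- ncol(X)

  qrx <- qr(X, tol = WLS_RANK_TOL)
  if (qrx$rank < p) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)

  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  piv <- qrx$pivot
  se <- numeric(p)
  se[piv] <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)

  structure(
    list(
      coefficients = beta,
      se = se,
      fitted = fitted,
      residuals = resid,
      sigma2 = sigma2,
      aicc = aicc_gwr(rss, n, p),
      adj_r2 = 1 - (rss / (n - p)) / (tss / (n - 1)),
      covariates = d$covariates,
      n = n
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d covariates, AICc = %.3f, adj R^2 = %.4f\n",
              x$n, length(x$covariates), x$aicc, x$adj_r2))
  invisible(x)
}

#' Default spacetime scale weights for a panel
#'
#' `lambda_s = 1`; `mu_t = tau^2` with `tau` the median nearest-neighbour
#' spatial distance among the panel's distinct cities, so one year of
#' temporal separation counts as much as a typical inter-city spacing.
#'
#' @param panel Panel data frame with `city_id`, `u`, `v`.
#' @return List with `lambda_s`, `mu_t` and the spacing `tau` (km).
#' @export
st_scale_defaults <- function(panel) {
  pts <- unique(panel[, c("city_id", "u", "v")])
  if (nrow(pts) < 2) stop("need at least 2 distinct cities", call. = FALSE)
  dm <- as.matrix(dist(pts[, c("u", "v")]))
  diag(dm) <- Inf
  tau <- median(apply(dm, 1, min))
  list(lambda_s = 1, mu_t = tau^2, tau = tau)
}
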