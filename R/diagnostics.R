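# Pre- and post-fit diagnostics: spatial weights, Moran's I with permutation
# inference, the IQR-vs-2SE nonstationarity test, and coefficient summary
# tables.

#' Build a spatial weight matrix
#'
#' `k-nearest`: binary k-nearest-neighbour adjacency symmetrized by union.
#' `inverse-distance`: `1/d` for pairs within `cutoff`, 0 beyond. The
#' diagonal is always zero; optional row standardization rescales each
#' nonzero row to sum to one.
#'
#' @param points Data frame or matrix of unique point coordinates with
#'   columns `u`, `v` (>= 2 points).
#' @param scheme `"knn"` or `"idw"`.
#' @param k Number of neighbours (knn; must be `< n`).
#' @param cutoff Distance cutoff (idw).
#' @param row_standardize Rescale rows to sum to 1 (default `TRUE`).
#' @return An `n x n` matrix of class `spatial_weights` with attributes
#'   `scheme` and `row_standardized`.
#' @export
build_spatial_weights <- function(points, scheme = c("knn", "idw"), k = 5,
                                  cutoff = NULL, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  pts <- as.matrix(as.data.frame(points)[, c("u", "v")])
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  dm <- as.matrix(dist(pts))

  if (scheme == "knn") {
    if (k >= n) stop("`k` must be smaller than the number of points",
                     call. = FALSE)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(dm[i, ])[-1][seq_len(k)]  # self excluded (distance 0 first)
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))  # symmetrize by union
  } else {
    if (is.null(cutoff) || cutoff <= 0) {
      stop("inverse-distance weights need a positive `cutoff`", call. = FALSE)
    }
    W <- ifelse(dm > 0 & dm <= cutoff, 1 / dm, 0)
  }
  diag(W) <- 0

  if (row_standardize) {
    rs <- rowSums(W)
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  structure(W, scheme = scheme, row_standardized = row_standardize,
            class = c("spatial_weights", "matrix", "array"))
}

#' Global Moran's I
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
#'   \quad z = x - \bar x, \quad S_0 = \sum_{ij} w_{ij}.}
#'
#' @param values Numeric vector with positive variance, length matching `W`.
#' @param W Spatial weight matrix (zero diagonal).
#' @return The statistic (expectation `-1/(n-1)` under exchangeability).
#' @export
morans_i <- function(values, W) {
  W <- unclass(W)
  n <- length(values)
  if (nrow(W) != n || ncol(W) != n) {
    stop("`W` must be an n x n matrix matching `values`", call. = FALSE)
  }
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) {
    stop("Moran's I is undefined for a constant vector (zero variance)",
         call. = FALSE)
  }
  s0 <- sum(W)
  (n / s0) * drop(crossprod(z, W %*% z)) / denom
}

#' Permutation p-value for Moran's I
#'
#' Random relabelings of the values over the locations give the permutation
#' null; the p-value is `(1 + #as-or-more-extreme) / (1 + n_perm)`.
#' "Extreme" is measured from the null expectation `-1/(n-1)`: one-sided
#' (`greater`) counts permuted statistics at or above the observed one,
#' two-sided counts permuted statistics at least as far from the expectation.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed (deterministic p-value).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return List: `i` (observed), `p_value`, `n_perm`, `perm_i` (the permuted
#'   statistics), `alternative`, `seed`.
#' @export
morans_i_pvalue <- function(values, W, n_perm = 999, seed = 1,
                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("`n_perm` must be at least 99", call. = FALSE)
  i_obs <- morans_i(values, W)
  n <- length(values)
  e_i <- -1 / (n - 1)

  perm_i <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) morans_i(sample(values), W),
           numeric(1))
  })
  extreme <- if (alternative == "greater") {
    sum(perm_i >= i_obs)
  } else {
    sum(abs(perm_i - e_i) >= abs(i_obs - e_i))
  }
  list(i = i_obs, p_value = (1 + extreme) / (1 + n_perm), n_perm = n_perm,
       perm_i = perm_i, alternative = alternative, seed = seed)
}

#' Spatial nonstationarity test
#'
#' For every coefficient (intercept included), compares the interquartile
#' range of the GTWR local coefficients with twice the OLS standard error of
#' the same coefficient; an IQR exceeding 2 SE flags variation beyond what a
#' stationary model would produce.
#'
#' @param gtwr A [fit_gtwr()] result.
#' @param ols A [fit_ols()] result on the same design.
#' @return Data frame: `variable`, `iqr`, `two_se`, `nonstationary`.
#' @export
nonstationarity_test <- function(gtwr, ols) {
  stopifnot(inherits(gtwr, "gtwr_fit"), inherits(ols, "ols_fit"))
  vars <- colnames(gtwr$coefficients)
  if (!identical(vars, names(ols$coefficients))) {
    stop("GTWR and OLS fits have different covariate orderings",
         call. = FALSE)
  }
  iqr <- apply(gtwr$coefficients, 2, function(b) {
    q <- quantile(b, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  two_se <- 2 * ols$se[vars]
  data.frame(variable = vars, iqr = unname(iqr), two_se = unname(two_se),
             nonstationary = unname(iqr > two_se))
}

#' Summarize local coefficients
#'
#' Per-variable mean, minimum, lower quartile, median, upper quartile and
#' maximum of the local GTWR coefficients (linear-interpolation quantiles).
#'
#' @param gtwr A [fit_gtwr()] result with at least 4 observations.
#' @return Data frame with columns `variable`, `AVG`, `MIN`, `LQ`, `MED`,
#'   `UQ`, `MAX`.
#' @export
summarize_coefficients <- function(gtwr) {
  stopifnot(inherits(gtwr, "gtwr_fit"))
  if (gtwr$n < 4) stop("need at least 4 observations", call. = FALSE)
  stats <- apply(gtwr$coefficients, 2, function(b) {
    q <- quantile(b, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(AVG = mean(b), MIN = min(b), LQ = q[1], MED = q[2], UQ = q[3],
      MAX = max(b))
  })
  out <- data.frame(variable = colnames(stats), t(stats))
  rownames(out) <- NULL
  out
}

#' Period-averaged local coefficients
#'
#' Unweighted means of the local coefficients over observations before
#' (`t < split_year`) and during (`t >= split_year`) a split such as the
#' pandemic onset, plus the change (during minus before).
#'
#' @param gtwr A [fit_gtwr()] result.
#' @param split_year First year of the "during" period (default 2020).
#' @return Data frame: `variable`, `before_mean`, `during_mean`, `change`.
#' @export
period_average_coefficients <- function(gtwr, split_year = 2020) {
  stopifnot(inherits(gtwr, "gtwr_fit"))
  before <- gtwr$obs$t < split_year
  during <- !before
  if (!any(before) || !any(during)) {
    stop(sprintf("both periods must be non-empty at split_year = %d",
                 split_year), call. = FALSE)
  }
  bm <- colMeans(gtwr$coefficients[before, , drop = FALSE])
  dm <- colMeans(gtwr$coefficients[during, , drop = FALSE])
  data.frame(variable = colnames(gtwr$coefficients),
             before_mean = unname(bm), during_mean = unname(dm),
             change = unname(dm - bm))
}

#' Assemble the full diagnostics report
#'
#' Bundles Moran's I (computed by default on city-level mean HPA with
#' k-nearest row-standardized weights), the nonstationarity test, the
#' coefficient quantile summary and the period-averaged coefficients into one
#' serializable report.
#'
#' @param panel Panel data frame (for the Moran's I input).
#' @param gtwr,ols Fitted models on that panel.
#' @param k Neighbours for the Moran's I weights.
#' @param n_perm Permutations for the Moran's I p-value.
#' @param seed Seed for the permutation draw.
#' @param split_year Period split passed to [period_average_coefficients()].
#' @return A list of class `diagnostics_report`.
#' @export
diagnostics_report <- function(panel, gtwr, ols, k = 5, n_perm = 999,
                               seed = 1, split_year = 2020) {
  cities <- unique(panel[, c("city_id", "u", "v")])
  mean_y <- tapply(panel$y, panel$city_id, mean)
  values <- as.numeric(mean_y[as.character(cities$city_id)])
  W <- build_spatial_weights(cities, scheme = "knn", k = k,
                             row_standardize = TRUE)
  mi <- morans_i_pvalue(values, W, n_perm = n_perm, seed = seed,
                        alternative = "greater")
  structure(
    list(
      morans_i = list(i = mi$i, p_value = mi$p_value, n_perm = mi$n_perm,
                      seed = seed, alternative = mi$alternative,
                      weights = sprintf("knn(k=%d), row-standardized", k)),
      nonstationarity = nonstationarity_test(gtwr, ols),
      coefficient_summary = summarize_coefficients(gtwr),
      period_averages = period_average_coefficients(gtwr, split_year),
      model_comparison = data.frame(
        model = c("GTWR", "OLS"),
        aicc = c(gtwr$aicc, ols$aicc),
        adj_r2 = c(gtwr$adj_r2, ols$adj_r2)
      )
    ),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (permutation p = %.4g, %s)\n",
              x$morans_i$i, x$morans_i$p_value, x$morans_i$weights))
  cat(sprintf("GTWR AICc = %.3f, adj R^2 = %.4f; OLS AICc = %.3f, adj R^2 = %.4f\n",
              x$model_comparison$aicc[1], x$model_comparison$adj_r2[1],
              x$model_comparison$aicc[2], x$model_comparison$adj_r2[2]))
  cat(sprintf("Nonstationary coefficients: %d of %d\n",
              sum(x$nonstationarity$nonstationary),
              nrow(x$nonstationarity)))
  invisible(x)
}
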