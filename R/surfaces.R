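# Closed-form coefficient surfaces beta(u, v, t) for the synthetic panel
# generator. Every constructor returns a vectorized function of (u, v, t);
# any user-supplied function with that signature is accepted too.

#' Coefficient surface constructors
#'
#' Build closed-form coefficient surfaces \eqn{\beta(u, v, t)} for the
#' synthetic panel generator: constant, linear in space and time, radial
#' decay away from a centre (e.g. the capital city), a step change at a
#' given year (the pandemic split), or a sum of surfaces.
#'
#' @param value,base Constant level of the surface.
#' @param du,dv,dt Linear slopes per km (space) and per year (time).
#' @param u0,v0,t0 Origin the linear terms are measured from.
#' @param scale Peak added at the centre of a radial surface.
#' @param range_km e-folding distance of the radial decay, km.
#' @param centre Length-2 vector `c(u, v)` of the radial centre.
#' @param delta Amount added where `t >= year`.
#' @param year Step year; observations with `t >= year` get `base + delta`.
#' @param ... Surfaces to add together.
#'
#' @return A function `f(u, v, t)` returning the surface value, vectorized
#'   over its arguments.
#' @examples
#' s <- surface_sum(surface_constant(0.19), surface_step(0, 0.027, 2020))
#' s(0, 0, c(2018, 2021))
#' @name surfaces
NULL

#' @rdname surfaces
#' @export
surface_constant <- function(value) {
  force(value)
  function(u, v, t) rep_len(value, max(length(u), length(v), length(t)))
}

#' @rdname surfaces
#' @export
surface_linear <- function(base, du = 0, dv = 0, dt = 0,
                           u0 = 0, v0 = 0, t0 = 0) {
  force(base); force(du); force(dv); force(dt)
  force(u0); force(v0); force(t0)
  function(u, v, t) base + du * (u - u0) + dv * (v - v0) + dt * (t - t0)
}

#' @rdname surfaces
#' @export
surface_radial <- function(scale, range_km, centre, base = 0) {
  stopifnot(length(centre) == 2, range_km > 0)
  force(scale); force(range_km); force(centre); force(base)
  function(u, v, t) {
    d <- sqrt((u - centre[1])^2 + (v - centre[2])^2)
    base + scale * exp(-d / range_km)
  }
}

#' @rdname surfaces
#' @export
surface_step <- function(base, delta, year = 2020) {
  force(base); force(delta); force(year)
  function(u, v, t) base + delta * (t >= year)
}

#' @rdname surfaces
#' @export
surface_sum <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0, all(vapply(parts, is.function, logical(1))))
  function(u, v, t) {
    out <- parts[[1]](u, v, t)
    for (p in parts[-1]) out <- out + p(u, v, t)
    out
  }
}

#' Bundle coefficient surfaces into a surface set
#'
#' A surface set holds the intercept surface, one surface per covariate, and
#' the residual noise standard deviation; [generate_panel()] evaluates it at
#' every (city, year) to build the dependent variable.
#'
#' @param intercept Function `f(u, v, t)` for the intercept surface.
#' @param beta Named list of surface functions, one per covariate.
#' @param noise_sd Standard deviation of the iid Gaussian error term (>= 0).
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(intercept, beta, noise_sd) {
  stopifnot(is.function(intercept), is.list(beta))
  if (length(beta) > 0 && (is.null(names(beta)) || any(names(beta) == ""))) {
    stop("every element of `beta` must be named after its covariate",
         call. = FALSE)
  }
  if (!all(vapply(beta, is.function, logical(1)))) {
    stop("every element of `beta` must be a function(u, v, t)", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  }
  structure(list(intercept = intercept, beta = beta, noise_sd = noise_sd),
            class = "surface_set")
}
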