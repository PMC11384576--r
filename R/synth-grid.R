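#' Generate a synthetic city grid
#'
#' Places `n_cities` points uniformly at random in the square
#' `[0, extent_km]^2` of projected planar coordinates (km) and designates the
#' city nearest the square's centroid as the political "capital". The grid
#' stands in for a national frame of prefecture-level cities when no real
#' geography is available.
#'
#' @param n_cities Number of cities (>= 2).
#' @param extent_km Side length of the square study region, in km.
#' @param seed Integer seed; identical arguments and seed give an identical
#'   grid.
#'
#' @return A `data.frame` of class `city_grid` with columns `city_id`, `u`
#'   (easting, km) and `v` (northing, km), and attribute `capital_id`.
#' @examples
#' g <- generate_city_grid(50, extent_km = 1000, seed = 1)
#' attr(g, "capital_id")
#' @export
generate_city_grid <- function(n_cities, extent_km, seed) {
  check_positive_scalar(n_cities, "n_cities")
  check_positive_scalar(extent_km, "extent_km")
  if (n_cities < 2) stop("`n_cities` must be at least 2", call. = FALSE)
  n_cities <- as.integer(n_cities)

  grid <- with_seed(seed, {
    data.frame(
      city_id = seq_len(n_cities),
      u = runif(n_cities, 0, extent_km),
      v = runif(n_cities, 0, extent_km)
    )
  })
  centre <- extent_km / 2
  d2 <- (grid$u - centre)^2 + (grid$v - centre)^2
  attr(grid, "capital_id") <- grid$city_id[which.min(d2)]
  attr(grid, "extent_km") <- extent_km
  class(grid) <- c("city_grid", "data.frame")
  grid
}

#' @export
print.city_grid <- function(x, ...) {
  cat(sprintf("City grid: %d cities on [0, %g] km^2, capital city %d\n",
              nrow(x), attr(x, "extent_km"), attr(x, "capital_id")))
  NextMethod()
}
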