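#' Build a random patchy landscape on a linear temperature gradient
#'
#' Patches are placed uniformly at random inside an `extent_km` x `width_km`
#' rectangle. Baseline temperature decreases linearly along the gradient axis
#' `x` (warm edge at `x = 0`), spanning exactly `gradient_span_C` between the
#' two ends of the rectangle; elevation increases linearly with `x` up to
#' `elevation_span_m`, so the thermal gradient can be read as an elevational
#' one.
#'
#' @param n_patches number of patches (>= 2).
#' @param extent_km length of the gradient axis in km.
#' @param width_km cross-gradient width in km.
#' @param gradient_span_C temperature span (degrees C) between `x = 0` and
#'   `x = extent_km`.
#' @param elevation_span_m elevation span (m) over the same extent.
#' @param T_warm baseline temperature at the warm edge (`x = 0`), degrees C.
#'   Only temperature differences matter for the dynamics; the anchor is
#'   arbitrary.
#' @return an object of class `ms_landscape`: a list with a `patches` data
#'   frame (`id`, `x`, `y` in km, `elevation` in m, `T_base` in degrees C),
#'   the geometry parameters, and the inter-patch distance matrix in metres.
#' @examples
#' set.seed(1)
#' L <- build_landscape(10)
#' range(L$patches$T_base)
#' @export
build_landscape <- function(n_patches = 50, extent_km = 50, width_km = 5,
                            gradient_span_C = 6, elevation_span_m = 900,
                            T_warm = 14) {
  if (n_patches < 2) stop("invalid configuration: n_patches must be >= 2")
  if (extent_km <= 0 || width_km <= 0 || gradient_span_C <= 0)
    stop("invalid configuration: landscape dimensions must be positive")
  x <- stats::runif(n_patches, 0, extent_km)
  y <- stats::runif(n_patches, 0, width_km)
  patches <- data.frame(
    id = seq_len(n_patches),
    x = x,
    y = y,
    elevation = elevation_span_m * x / extent_km,
    T_base = T_warm - gradient_span_C * x / extent_km
  )
  dist_m <- 1000 * as.matrix(stats::dist(cbind(x, y)))
  structure(
    list(patches = patches, extent_km = extent_km, width_km = width_km,
         gradient_span_C = gradient_span_C,
         elevation_span_m = elevation_span_m, T_warm = T_warm,
         dist_m = dist_m),
    class = "ms_landscape"
  )
}

#' Sigmoidal climate forcing
#'
#' Defines the warming trajectory: a logistic curve renormalised so that the
#' temperature increment is exactly 0 at the onset of warming and exactly
#' `delta_total_C` at `duration_y` years, with its inflection at `t_mid`.
#'
#' @param delta_total_C total warming (degrees C) delivered over the warming
#'   period.
#' @param duration_y length of the warming period in years.
#' @param k logistic steepness (1/years).
#' @param t_mid inflection year; defaults to the midpoint of the period.
#' @return an object of class `ms_forcing`.
#' @examples
#' f <- climate_forcing()
#' forcing_at(f, c(0, 75, 150, 200))
#' @export
climate_forcing <- function(delta_total_C = 3, duration_y = 150, k = 0.08,
                            t_mid = duration_y / 2) {
  if (duration_y <= 0 || k <= 0) stop("invalid configuration: forcing")
  structure(
    list(delta_total_C = delta_total_C, duration_y = duration_y, k = k,
         t_mid = t_mid),
    class = "ms_forcing"
  )
}

#' Warming increment at a given time
#'
#' Evaluates the renormalised sigmoid: 0 for `t <= 0` (stable phase),
#' `delta_total_C` for `t >= duration_y`, and
#' `delta * (s(t) - s(0)) / (s(duration) - s(0))` in between, with
#' `s(t) = 1 / (1 + exp(-k (t - t_mid)))`. The same increment applies to
#' every patch: forcing is spatially uniform.
#'
#' @param forcing an `ms_forcing` object.
#' @param t years since the onset of warming (may be a vector; negative
#'   values denote the stable phase).
#' @return warming increment(s) in degrees C.
#' @export
forcing_at <- function(forcing, t) {
  s <- function(u) 1 / (1 + exp(-forcing$k * (u - forcing$t_mid)))
  s0 <- s(0)
  sD <- s(forcing$duration_y)
  out <- forcing$delta_total_C * (s(t) - s0) / (sD - s0)
  out[t <= 0] <- 0
  out[t >= forcing$duration_y] <- forcing$delta_total_C
  out
}

#' Patch temperatures at a given time
#'
#' @param landscape an `ms_landscape` object.
#' @param t years since the onset of warming (scalar).
#' @param forcing an `ms_forcing` object, or `NULL` for baseline
#'   temperatures.
#' @return vector of patch temperatures (degrees C).
#' @export
temperature_at <- function(landscape, t = 0, forcing = NULL) {
  inc <- if (is.null(forcing)) 0 else forcing_at(forcing, t)
  landscape$patches$T_base + inc
}

#' @export
print.ms_landscape <- function(x, ...) {
  cat(sprintf(
    "Landscape: %d patches on %g x %g km, %g degC gradient (%g m elevation)\n",
    nrow(x$patches), x$extent_km, x$width_km, x$gradient_span_C,
    x$elevation_span_m))
  invisible(x)
}

# Mean nearest-neighbour distance between patches (m); the downslope species
# pool sits at half this distance beyond the warm edge.
mean_nn_distance <- function(landscape) {
  d <- landscape$dist_m
  diag(d) <- Inf
  mean(apply(d, 1, min))
}
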