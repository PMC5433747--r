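#' Gaussian temperature-dependent growth rate
#'
#' `r(T) = r_max * exp(-(T - T_opt)^2 / (2 sigma_opt^2))`: a species grows
#' at its common maximum rate where the experienced temperature matches its
#' thermal optimum, and increasingly slowly the further temperature departs
#' from it. The niche width `sigma_opt` is shared by all species.
#'
#' @param T experienced temperature (degrees C); vectorised.
#' @param T_opt thermal optimum (degrees C); vectorised.
#' @param r_max maximum daily growth rate (1/day).
#' @param sigma_opt thermal niche width (degrees C).
#' @return per-day growth rate(s), in `(0, r_max]`.
#' @export
growth_rate <- function(T, T_opt, r_max = 0.05, sigma_opt = 3) {
  stopifnot(r_max > 0, sigma_opt > 0)
  r_max * exp(-(T - T_opt)^2 / (2 * sigma_opt^2))
}

#' Temperature-dependent carrying capacity
#'
#' Carrying capacity is proportional to the temperature-dependent growth
#' rate, `K = K_max * r(T)/r_max`, floored at `K_floor` to keep the
#' density-dependent term finite far from the optimum.
#'
#' @inheritParams growth_rate
#' @param K_max carrying capacity at the thermal optimum (biomass units).
#' @param K_floor minimum carrying capacity.
#' @return carrying capacity in biomass units.
#' @export
carrying_capacity <- function(T, T_opt, r_max = 0.05, sigma_opt = 3,
                              K_max = 100, K_floor = 1e-4 * K_max) {
  stopifnot(K_max > 0, K_floor > 0)
  pmax(K_max * growth_rate(T, T_opt, r_max, sigma_opt) / r_max, K_floor)
}

#' One daily Lotka-Volterra step
#'
#' Discrete-time update for all species in one patch:
#' `B_i' = B_i + r_i (1 - B_i/K_i - alpha * sum_{j != i} B_j/K_j) B_i -
#' m B_i`, with intraspecific coefficient 1, a common interspecific
#' coefficient `alpha < 1` (allowing coexistence), and a daily background
#' loss `m` (herbivory, pathogens). Negative results are clamped to zero.
#' This is the plain R reference implementation; the season loop uses the
#' compiled equivalent.
#'
#' @param B biomass vector over species (>= 0).
#' @param r per-species daily growth rates.
#' @param K per-species carrying capacities.
#' @param alpha common interspecific competition coefficient in `[0, 1)`.
#' @param m daily background loss rate.
#' @return updated biomass vector.
#' @export
lv_day_step <- function(B, r, K, alpha, m = 0.001) {
  if (length(r) != length(B) || length(K) != length(B))
    stop("B, r and K must have equal length")
  bk <- B / K
  tot <- sum(bk)
  out <- B + r * (1 - bk - alpha * (tot - bk)) * B - m * B
  pmax(out, 0)
}

#' Run one growing season in every patch
#'
#' Applies `season_days` daily Lotka-Volterra updates at constant
#' temperature; at season end any biomass below `extinction_threshold` is
#' zeroed, defining local presence/absence.
#'
#' @param B patch x species starting-biomass matrix.
#' @param r,K patch x species growth-rate and carrying-capacity matrices for
#'   the current temperatures.
#' @param alpha common interspecific competition coefficient.
#' @param m daily background loss rate.
#' @param season_days length of the growing season in days.
#' @param extinction_threshold biomass below which a species is locally
#'   extinct at season end.
#' @return patch x species end-of-season biomass matrix.
#' @export
run_growing_season <- function(B, r, K, alpha, m = 0.001, season_days = 120,
                               extinction_threshold = 0.55) {
  cpp_run_season(B, r, K, alpha, m, as.integer(season_days),
                 extinction_threshold)
}
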