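#' Assign thermal niche optima
#'
#' Optima are evenly spaced across the landscape's baseline temperature range
#' extended by `extension_C` on both sides, so that the warm edge can be
#' supplied by warmer-adapted species (the downslope pool) and the cold edge
#' holds colder-adapted species than ever experienced. Returned sorted
#' ascending.
#'
#' @param n_species number of species (>= 2).
#' @param landscape an `ms_landscape` object.
#' @param extension_C margin (degrees C) beyond the realised baseline
#'   temperature extremes; default 2.
#' @return numeric vector of length `n_species` (degrees C).
#' @export
assign_thermal_optima <- function(n_species, landscape, extension_C = 2) {
  stopifnot(n_species >= 2, extension_C >= 0)
  tb <- landscape$patches$T_base
  seq(min(tb) - extension_C, max(tb) + extension_C, length.out = n_species)
}

#' Moment-matched lognormal parameters
#'
#' Converts an arithmetic mean and standard deviation (both in mg) into the
#' `(meanlog, sdlog)` parameters of the lognormal distribution with those
#' moments: `sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param mean_mg arithmetic mean seed mass (mg), > 0.
#' @param sd_mg arithmetic standard deviation (mg), > 0.
#' @return list with `meanlog` and `sdlog`.
#' @examples
#' p <- lognormal_params(1.5, 3)
#' exp(p$meanlog + p$sdlog^2 / 2) # = 1.5
#' @export
lognormal_params <- function(mean_mg, sd_mg) {
  if (mean_mg <= 0) stop("invalid trait: mean_mg must be positive")
  if (sd_mg <= 0)
    stop("degenerate seed-mass distribution: sd_mg must be positive ",
         "(use the uniform scenario for equal seed masses)")
  s2 <- log(1 + sd_mg^2 / mean_mg^2)
  list(meanlog = log(mean_mg) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample species seed masses
#'
#' Uniform scenario: every species gets the distribution mean (the degenerate
#' SD = 0 case). Variable and trade-off scenarios: i.i.d. draws from the
#' moment-matched lognormal.
#'
#' @param scenario one of `"uniform"`, `"variable"`, `"tradeoff"`.
#' @param n_species number of species.
#' @param sm_mean_mg,sm_sd_mg arithmetic mean and SD of the seed-mass
#'   distribution (mg).
#' @return numeric vector of seed masses (mg).
#' @export
sample_seed_masses <- function(scenario, n_species, sm_mean_mg = 1.5,
                               sm_sd_mg = 3) {
  scenario <- match.arg(scenario, c("uniform", "variable", "tradeoff"))
  if (scenario == "uniform" || sm_sd_mg == 0)
    return(rep(sm_mean_mg, n_species))
  p <- lognormal_params(sm_mean_mg, sm_sd_mg)
  stats::rlnorm(n_species, p$meanlog, p$sdlog)
}

# Demographic scaling rules (seed-mass/seed-number trade-off defaults):
# fecundity f(SM) = phi / SM   -- strict size-number trade-off, f*SM = phi
# germination g(SM) = g_min + (g_max - g_min) * SM / (SM + sm_half)
# seedling biomass b0(SM) = kappa * SM^seedling_exponent
demography_rules <- function(SM, phi, g_min, g_max, sm_half, kappa,
                             seedling_exponent) {
  list(
    fecundity = phi / SM,
    germ_p = g_min + (g_max - g_min) * SM / (SM + sm_half),
    seedling_b = kappa * SM^seedling_exponent
  )
}

#' Derive scenario-dependent demography from seed mass
#'
#' The dispersal scale `beta` (and hence the mean dispersal distance
#' `delta`) is always computed from each species' own seed mass. The
#' remaining vital rates depend on the scenario:
#' \describe{
#'   \item{uniform}{all species share one seed mass, so all rates are equal.}
#'   \item{variable}{fecundity, germination probability and seedling biomass
#'     are computed from the distribution median `exp(meanlog)` and are
#'     identical across species; seed mass affects dispersal only.}
#'   \item{tradeoff}{all rates are computed from each species' own seed
#'     mass: larger seeds mean fewer seeds per unit biomass but higher
#'     germination probability and heavier seedlings.}
#' }
#'
#' @param SM vector of seed masses (mg), all > 0.
#' @param scenario one of `"uniform"`, `"variable"`, `"tradeoff"`.
#' @param sm_mean_mg,sm_sd_mg parameters of the seed-mass distribution (used
#'   for the variable scenario's reference median).
#' @param phi reproductive-mass budget: seed output (mg) per unit biomass.
#' @param g_min,g_max,sm_half saturating germination-probability parameters.
#' @param kappa,seedling_exponent seedling-biomass allometry.
#' @param kernel_a,kernel_c,sm_exponent dispersal-kernel scaling (see
#'   [beta_from_sm()]).
#' @return data frame with columns `SM`, `fecundity`, `germ_p`,
#'   `seedling_b`, `beta`, `delta`.
#' @export
derive_demography <- function(SM, scenario, sm_mean_mg = 1.5, sm_sd_mg = 3,
                              phi = 20, g_min = 0.3, g_max = 0.8,
                              sm_half = 1, kappa = 2.2,
                              seedling_exponent = 0.68,
                              kernel_a = 600, kernel_c = 0.5,
                              sm_exponent = -0.13) {
  if (any(SM <= 0)) stop("invalid trait: seed mass must be positive")
  scenario <- match.arg(scenario, c("uniform", "variable", "tradeoff"))
  sm_ref <- switch(scenario,
    uniform = SM,
    variable = rep(exp(lognormal_params(sm_mean_mg, sm_sd_mg)$meanlog),
                   length(SM)),
    tradeoff = SM
  )
  dem <- demography_rules(sm_ref, phi, g_min, g_max, sm_half, kappa,
                          seedling_exponent)
  beta <- beta_from_sm(SM, a = kernel_a, c = kernel_c,
                       sm_exponent = sm_exponent)
  data.frame(SM = SM, fecundity = dem$fecundity, germ_p = dem$germ_p,
             seedling_b = dem$seedling_b, beta = beta,
             delta = mean_dispersal_distance(beta, kernel_c))
}

#' Generate the full species trait table
#'
#' Combines evenly spaced thermal optima with scenario-dependent seed masses
#' and demography.
#'
#' @param config an `ms_config` object (see [ms_config()]).
#' @param landscape an `ms_landscape` object.
#' @return an object of class `ms_traits`: a data frame with one row per
#'   species (`species_id`, `T_opt`, `SM`, `fecundity`, `germ_p`,
#'   `seedling_b`, `beta`, `delta`).
#' @export
species_traits <- function(config, landscape) {
  T_opt <- assign_thermal_optima(config$n_species, landscape,
                                 config$topt_extension_C)
  SM <- sample_seed_masses(config$scenario, config$n_species,
                           config$sm_mean_mg, config$sm_sd_mg)
  dem <- derive_demography(SM, config$scenario,
                           sm_mean_mg = config$sm_mean_mg,
                           sm_sd_mg = config$sm_sd_mg,
                           phi = config$phi, g_min = config$g_min,
                           g_max = config$g_max, sm_half = config$sm_half,
                           kappa = config$kappa,
                           seedling_exponent = config$seedling_exponent,
                           kernel_a = config$kernel_a,
                           kernel_c = config$kernel_c,
                           sm_exponent = config$sm_exponent)
  out <- cbind(data.frame(species_id = seq_len(config$n_species),
                          T_opt = T_opt), dem)
  class(out) <- c("ms_traits", "data.frame")
  out
}
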