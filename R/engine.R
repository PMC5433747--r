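# Yearly loop orchestration: growing season -> seed production -> dispersal
# (+ downslope-pool immigration) -> germination; adults die after dispersal.

# Growth-rate and carrying-capacity matrices (patch x species) at the given
# patch temperatures.
rate_matrices <- function(T_patch, traits, config) {
  dT <- outer(T_patch, traits$T_opt, "-")
  r <- config$r_max * exp(-dT^2 / (2 * config$sigma_opt^2))
  K <- pmax(config$K_max * r / config$r_max,
            config$K_floor_frac * config$K_max)
  list(r = r, K = K)
}

#' Initialise a simulation run
#'
#' Builds the landscape and trait table from the current RNG state and
#' populates every patch with every species at equal initial biomass
#' (default `K_max / (2 n_species)`).
#'
#' @param config an `ms_config` object.
#' @return list with `landscape`, `traits`, `D` (dispersal array), `B`
#'   (initial patch x species biomass), and `pool_offset_m`.
#' @export
initialize_run <- function(config) {
  landscape <- build_landscape(config$n_patches, config$extent_km,
                               config$width_km, config$gradient_span_C,
                               config$elevation_span_m, config$T_warm)
  traits <- species_traits(config, landscape)
  D <- build_dispersal_matrix(landscape, traits$beta, config$kernel_c,
                              config$r_capture_m)
  b0 <- if (is.na(config$b_init)) config$K_max / (2 * config$n_species)
        else config$b_init
  B <- matrix(b0, nrow = config$n_patches, ncol = config$n_species)
  list(landscape = landscape, traits = traits, D = D, B = B,
       pool_offset_m = mean_nn_distance(landscape) / 2)
}

# Immigrant seed input from the downslope pool, given this year's
# end-of-season communities.
pool_seed_input <- function(B_end, run, config) {
  traits <- run$traits
  v <- mean_community_topt_var(B_end, traits$T_opt)
  if (!is.finite(v) || v <= 0) return(NULL)
  tot <- rowSums(B_end)
  donor_seed_matrix(B_end, traits, run$landscape$patches$x,
                    run$pool_offset_m, mean(tot[tot > 0]), v,
                    config$kernel_c, config$r_capture_m)
}

#' Advance the metacommunity by one year
#'
#' Runs the growing season at the given patch temperatures, produces and
#' disperses seeds (adding pool immigration where enabled), and converts
#' germinants into next year's starting biomass.
#'
#' @param B patch x species starting biomass for the year.
#' @param T_patch per-patch temperatures for the year (degrees C).
#' @param run run context from [initialize_run()].
#' @param config an `ms_config` object.
#' @return list with `B_end` (end-of-season biomass, the state on which all
#'   metrics are computed) and `B_next` (next year's starting biomass).
#' @export
step_year <- function(B, T_patch, run, config) {
  rk <- rate_matrices(T_patch, run$traits, config)
  B_end <- run_growing_season(B, rk$r, rk$K, config$alpha, config$m,
                              config$season_days,
                              config$extinction_threshold)
  seeds <- produce_seeds(B_end, run$traits$fecundity)
  pool_seeds <- if (config$pool_enabled) pool_seed_input(B_end, run, config)
                else NULL
  B_next <- disperse_and_establish(seeds, run$D, run$traits$germ_p,
                                   run$traits$seedling_b, pool_seeds)
  list(B_end = B_end, B_next = B_next)
}

#' Run the stable-climate phase to (near) equilibrium
#'
#' Iterates yearly dynamics at baseline temperatures until the maximum
#' year-over-year biomass change, relative to the largest biomass in the
#' system, stays below `stable_tol` for `stable_window` consecutive years,
#' or until `max_stable_years` is reached (then a warning is issued and the
#' run proceeds, equivalent to a fixed-length run-up). Native species are
#' those with a regionally viable population -- summed biomass above
#' `native_threshold` -- at termination; the same cutoff defines regional
#' richness (and hence extinction) throughout, so that vanishingly small
#' sink populations, which a deterministic model never drives to exact
#' zero, do not count as regional presences.
#'
#' @param run run context from [initialize_run()].
#' @param config an `ms_config` object.
#' @return list with `B` (next-year starting biomass), `B_end`
#'   (end-of-season biomass at equilibrium), `natives` (integer species
#'   ids), `years` run, and `converged` flag.
#' @export
run_stable_phase <- function(run, config) {
  T_patch <- run$landscape$patches$T_base
  B <- run$B
  B_end_prev <- NULL
  streak <- 0L
  converged <- FALSE
  years <- 0L
  while (years < config$max_stable_years) {
    years <- years + 1L
    st <- step_year(B, T_patch, run, config)
    if (!is.null(B_end_prev)) {
      denom <- max(B_end_prev, 1e-12)
      rel <- max(abs(st$B_end - B_end_prev)) / denom
      streak <- if (rel < config$stable_tol) streak + 1L else 0L
      if (streak >= config$stable_window) {
        converged <- TRUE
        B_end_prev <- st$B_end
        B <- st$B_next
        break
      }
    }
    B_end_prev <- st$B_end
    B <- st$B_next
  }
  if (!converged)
    warning("stable phase did not converge within ", config$max_stable_years,
            " years; proceeding with the final state")
  natives <- which(colSums(B_end_prev) > config$native_threshold)
  list(B = B, B_end = B_end_prev, natives = natives, years = years,
       converged = converged)
}

#' Run the climate-change phase
#'
#' Applies the sigmoidal warming over `warming_years`, logging colonisation
#' and exclusion events (presence changes between consecutive season ends),
#' then lets the system settle for `settling_years` at the final climate.
#'
#' @param B starting biomass at warming onset (next-year germinants from the
#'   equilibrium state).
#' @param B_end_stable end-of-season biomass at equilibrium (reference for
#'   the first year's events).
#' @param run run context from [initialize_run()].
#' @param config an `ms_config` object.
#' @return list with final `B_end`, final patch temperatures `T_patch`,
#'   accumulated event count matrices `events`, and a yearly record data
#'   frame (`year`, `gamma_richness`, `gamma_div` over all species).
#' @export
run_climate_change <- function(B, B_end_stable, run, config) {
  forcing <- climate_forcing(config$warming_C, config$warming_years,
                             config$sigmoid_k)
  P <- config$n_patches
  S <- config$n_species
  col_counts <- matrix(0, P, S)
  exc_counts <- matrix(0, P, S)
  prev_presence <- B_end_stable > config$extinction_threshold
  total_years <- config$warming_years + config$settling_years
  yearly <- data.frame(year = seq_len(total_years),
                       gamma_richness = NA_real_, gamma_div = NA_real_)
  B_end <- B_end_stable
  for (t in seq_len(total_years)) {
    T_patch <- run$landscape$patches$T_base + forcing_at(forcing, t)
    st <- step_year(B, T_patch, run, config)
    B_end <- st$B_end
    B <- st$B_next
    presence <- B_end > config$extinction_threshold
    if (t <= config$warming_years) {
      ev <- presence_events(prev_presence, presence)
      col_counts <- col_counts + ev$colonisations
      exc_counts <- exc_counts + ev$exclusions
    }
    prev_presence <- presence
    reg <- colSums(B_end)
    yearly$gamma_richness[t] <- sum(reg > config$extinction_threshold)
    yearly$gamma_div[t] <- inverse_simpson(reg)
  }
  list(B_end = B_end, T_patch = run$landscape$patches$T_base +
         forcing_at(forcing, total_years),
       events = list(colonisations = col_counts, exclusions = exc_counts),
       yearly = yearly)
}

# Response-variable summary of one state, restricted to native species.
summarize_state <- function(B_end, T_patch, run, config, natives) {
  Bn <- B_end[, natives, drop = FALSE]
  pres <- Bn > config$extinction_threshold
  div <- diversity_partition(Bn)
  reg <- colSums(Bn)
  lag <- climate_lag(B_end, T_patch, run$traits, natives)
  list(
    local_richness_mean = mean(rowSums(pres)),
    regional_richness = sum(reg > config$native_threshold),
    alpha_div = div$alpha, beta_div = div$beta, gamma_div = div$gamma,
    jaccard_mean = if (nrow(pres) >= 2) jaccard_mean(pres) else NA_real_,
    cwm_geomean_sm = if (sum(reg) > 0)
      weighted_geomean_sm(reg, run$traits$SM[natives]) else NA_real_,
    lag_mean_C = lag$mean_abs_lag,
    lag_sm_corr = lag$lag_sm_corr
  )
}

#' Simulate one metacommunity replicate
#'
#' The main single-run entry point: builds a random landscape and species
#' pool, runs the stable-climate phase to equilibrium, identifies native
#' species, imposes the sigmoidal warming plus a settling period, and
#' summarises richness, inverse-Simpson diversity, Jaccard dissimilarity,
#' events, seed-mass selection and climate-tracking lags before and after
#' climate change (native species only).
#'
#' @param config an `ms_config` object.
#' @param seed integer RNG seed for this replicate; defaults to the
#'   configuration's `base_seed`.
#' @return an object of class `metashift_sim`; see [summary.metashift_sim()].
#' @examples
#' \donttest{
#' cfg <- ms_config(n_species = 40, n_patches = 15, max_stable_years = 80)
#' sim <- metacommunity_sim(cfg, seed = 1)
#' summary(sim)
#' }
#' @export
metacommunity_sim <- function(config = ms_config(),
                              seed = config$base_seed) {
  set.seed(seed)
  run <- initialize_run(config)
  stable <- run_stable_phase(run, config)
  natives <- stable$natives
  T_base <- run$landscape$patches$T_base
  stable_metrics <- summarize_state(stable$B_end, T_base, run, config,
                                    natives)
  cc <- run_climate_change(stable$B, stable$B_end, run, config)
  post_metrics <- summarize_state(cc$B_end, cc$T_patch, run, config,
                                  natives)
  ev <- count_events(cc$events, natives, config$n_patches)
  out <- list(
    config = config, seed = seed, landscape = run$landscape,
    traits = run$traits, natives = natives,
    stable = c(stable_metrics,
               list(B_end = stable$B_end, years = stable$years,
                    converged = stable$converged)),
    post = c(post_metrics, list(B_end = cc$B_end, T_patch = cc$T_patch)),
    events = cc$events,
    colonisations_per_patch = ev$colonisations_per_patch,
    exclusions_per_patch = ev$exclusions_per_patch,
    pct_change_richness = percent_change(stable_metrics$regional_richness,
                                         post_metrics$regional_richness),
    pct_change_gamma_div = percent_change(stable_metrics$gamma_div,
                                          post_metrics$gamma_div),
    yearly = cc$yearly
  )
  class(out) <- "metashift_sim"
  out
}

#' Run replicated simulations
#'
#' Runs `n_replicates` independent replicates with seeds `base_seed + 1`,
#' `base_seed + 2`, ... and collects per-replicate response variables plus
#' their means. Fully reproducible given `base_seed`.
#'
#' @param config an `ms_config` object.
#' @param n_replicates number of replicates; defaults to the
#'   configuration's value.
#' @return an object of class `metashift_ensemble`: list with `summary`
#'   (one row per replicate) and `mean` (named vector of column means).
#' @export
run_replicates <- function(config = ms_config(),
                           n_replicates = config$n_replicates) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sim <- metacommunity_sim(config, seed = config$base_seed + i)
    rows[[i]] <- replicate_row(sim, i)
  }
  summary_df <- do.call(rbind, rows)
  num <- vapply(summary_df, is.numeric, logical(1))
  structure(
    list(config = config, summary = summary_df,
         mean = colMeans(summary_df[, num, drop = FALSE], na.rm = TRUE)),
    class = "metashift_ensemble"
  )
}

replicate_row <- function(sim, i) {
  s <- sim$stable
  p <- sim$post
  data.frame(
    replicate = i, seed = sim$seed, scenario = sim$config$scenario,
    alpha = sim$config$alpha, sm_mean_mg = sim$config$sm_mean_mg,
    sm_sd_mg = sim$config$sm_sd_mg,
    stable_years = s$years, stable_converged = s$converged,
    n_natives = length(sim$natives),
    stable_local_richness = s$local_richness_mean,
    stable_regional_richness = s$regional_richness,
    stable_alpha_div = s$alpha_div, stable_beta_div = s$beta_div,
    stable_gamma_div = s$gamma_div, stable_jaccard = s$jaccard_mean,
    stable_cwm_geomean_sm = s$cwm_geomean_sm,
    post_local_richness = p$local_richness_mean,
    post_regional_richness = p$regional_richness,
    post_alpha_div = p$alpha_div, post_beta_div = p$beta_div,
    post_gamma_div = p$gamma_div, post_jaccard = p$jaccard_mean,
    post_cwm_geomean_sm = p$cwm_geomean_sm,
    post_lag_mean_C = p$lag_mean_C, post_lag_sm_corr = p$lag_sm_corr,
    colonisations_per_patch = sim$colonisations_per_patch,
    exclusions_per_patch = sim$exclusions_per_patch,
    pct_change_richness = sim$pct_change_richness,
    pct_change_gamma_div = sim$pct_change_gamma_div
  )
}
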