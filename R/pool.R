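#' Extrapolate the downslope pool's community-weighted mean optimum
#'
#' Per-patch community-weighted mean (CWM) thermal optima are regressed on
#' gradient position by ordinary least squares, and the fit is evaluated at
#' the pool's position beyond the warm edge. Empty patches are excluded;
#' with fewer than two occupied patches the warmest occupied patch's CWM
#' (or, failing that, the warmest species optimum) is used as a fallback.
#'
#' @param B patch x species biomass matrix (end of season).
#' @param T_opt per-species thermal optima.
#' @param x_km per-patch gradient positions (km).
#' @param pool_x_km pool position on the gradient axis (km; negative values
#'   lie beyond the warm edge at `x = 0`).
#' @return extrapolated CWM thermal optimum (degrees C) at the pool.
#' @export
extrapolate_pool_cwm <- function(B, T_opt, x_km, pool_x_km) {
  tot <- rowSums(B)
  occ <- tot > 0
  if (sum(occ) < 2) {
    if (!any(occ)) return(max(T_opt))
    warm <- which(occ)[which.min(x_km[occ])]
    return(sum(B[warm, ] * T_opt) / tot[warm])
  }
  cwm <- as.vector(B[occ, , drop = FALSE] %*% T_opt) / tot[occ]
  x <- x_km[occ]
  # OLS of CWM on x, evaluated at pool_x_km
  mx <- mean(x); mc <- mean(cwm)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx > 0) sum((x - mx) * (cwm - mc)) / sxx else 0
  mc + slope * (pool_x_km - mx)
}

# Abundance-weighted variance of T_opt within each occupied patch, averaged
# over patches; sets the width of the pool's T_opt profile.
mean_community_topt_var <- function(B, T_opt) {
  tot <- rowSums(B)
  occ <- which(tot > 0)
  if (!length(occ)) return(NA_real_)
  v <- vapply(occ, function(p) {
    w <- B[p, ] / tot[p]
    mu <- sum(w * T_opt)
    sum(w * (T_opt - mu)^2)
  }, numeric(1))
  mean(v)
}

#' Compose the regional pool community
#'
#' The pool's abundance profile across species is a normal density over
#' thermal optima, centred on the extrapolated CWM with the given variance,
#' rescaled to a total biomass of `scale`.
#'
#' @param cwm_topt pool CWM thermal optimum (degrees C).
#' @param var_topt pool optimum variance (degrees C squared), > 0.
#' @param T_opt per-species thermal optima.
#' @param scale total pool biomass.
#' @return per-species abundance vector summing to `scale`.
#' @export
pool_community <- function(cwm_topt, var_topt, T_opt, scale) {
  stopifnot(var_topt > 0, scale >= 0)
  dens <- stats::dnorm(T_opt, mean = cwm_topt, sd = sqrt(var_topt))
  tot <- sum(dens)
  if (tot == 0 || scale == 0) return(numeric(length(T_opt)))
  dens / tot * scale
}

# Per-patch donor immigration: every patch has a virtual donor community
# directly downslope of it (offset_m away), with composition given by the
# OLS fit of CWM T_opt on gradient position evaluated at the donor's
# location and a common normal T_opt profile. In the landscape interior the
# donor essentially mirrors the local community; at the warm edge the
# regression extrapolates beyond the boundary, so novel warmer-adapted
# species enter the landscape there (no lowland attrition, no competitive
# release).
donor_seed_matrix <- function(B_end, traits, x_km, offset_m, scale,
                              var_topt, c, r_capture) {
  tot <- rowSums(B_end)
  occ <- tot > 0
  if (sum(occ) < 2 || var_topt <= 0 || scale <= 0) return(NULL)
  cwm <- as.vector(B_end[occ, , drop = FALSE] %*% traits$T_opt) / tot[occ]
  x <- x_km[occ]
  mx <- mean(x); mc <- mean(cwm)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx > 0) sum((x - mx) * (cwm - mc)) / sxx else 0
  donor_cwm <- mc + slope * (x_km - offset_m / 1000 - mx)
  # normal T_opt profile per donor, rescaled to the common pool biomass
  dens <- stats::dnorm(outer(donor_cwm, traits$T_opt, "-") / sqrt(var_topt))
  rs <- rowSums(dens)
  abund <- dens / ifelse(rs > 0, rs, 1) * scale
  p_arrive <- c / (2 * pi * traits$beta^2 * gamma(2 / c)) *
    exp(-(offset_m / traits$beta)^c) * pi * r_capture^2
  abund * rep(traits$fecundity * p_arrive, each = nrow(abund))
}

#' Seed immigration from the downslope pool
#'
#' A virtual donor community with the pool's composition is assumed to sit
#' `offset_m` downslope of every patch; its seed output (fecundity times
#' abundance) arrives with probability given by the species' own kernel
#' density at that distance times the capture area. Every patch therefore
#' receives the same immigrant seed vector.
#'
#' @param pool_abund per-species pool abundance (biomass).
#' @param fecundity per-species seeds per unit biomass.
#' @param beta per-species kernel scales (m).
#' @param offset_m distance from each patch to its virtual donor (m).
#' @param n_patches number of patches receiving immigration.
#' @param c kernel shape.
#' @param r_capture patch capture radius (m).
#' @return patch x species matrix of arriving immigrant seeds.
#' @export
pool_immigration <- function(pool_abund, fecundity, beta, offset_m,
                             n_patches, c = 0.5, r_capture = 50) {
  stopifnot(length(pool_abund) == length(fecundity),
            length(beta) == length(fecundity), offset_m > 0)
  p_arrive <- c / (2 * pi * beta^2 * gamma(2 / c)) *
    exp(-(offset_m / beta)^c) * pi * r_capture^2
  seeds <- fecundity * pool_abund * p_arrive
  matrix(seeds, nrow = n_patches, ncol = length(seeds), byrow = TRUE)
}
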