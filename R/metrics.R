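#' Inverse Simpson diversity
#'
#' `1 / sum(p_s^2)` with `p_s` the abundance shares: the effective number of
#' equally abundant species. Returns 0 for an all-zero vector (empty
#' community sentinel).
#'
#' @param abundances non-negative abundance vector.
#' @return effective species number (>= 1 for any non-empty community).
#' @examples
#' inverse_simpson(c(0.7, 0.3))
#' @export
inverse_simpson <- function(abundances) {
  stopifnot(all(abundances >= 0))
  tot <- sum(abundances)
  if (tot == 0) return(0)
  p <- abundances / tot
  1 / sum(p^2)
}

#' Alpha / beta / gamma diversity partition
#'
#' Multiplicative partition of regional inverse-Simpson diversity: `alpha`
#' is the mean inverse Simpson over occupied patches, `gamma` the inverse
#' Simpson of the pooled (column-sum) regional abundances, and
#' `beta = gamma / alpha`.
#'
#' @param B patch x species abundance matrix (restrict to native species
#'   before calling, if applicable).
#' @return list with `alpha`, `beta`, `gamma`.
#' @export
diversity_partition <- function(B) {
  occ <- rowSums(B) > 0
  if (!any(occ)) return(list(alpha = 0, beta = 0, gamma = 0))
  alpha <- mean(apply(B[occ, , drop = FALSE], 1, inverse_simpson))
  gamma <- inverse_simpson(colSums(B))
  list(alpha = alpha, beta = gamma / alpha, gamma = gamma)
}

#' Mean pairwise Jaccard dissimilarity between patches
#'
#' `1 - |A intersect B| / |A union B|` averaged over unordered patch pairs;
#' pairs of two empty patches contribute 0.
#'
#' @param presence patch x species logical (or 0/1) matrix.
#' @return mean dissimilarity in `[0, 1]`.
#' @export
jaccard_mean <- function(presence) {
  P <- nrow(presence)
  stopifnot(P >= 2)
  pres <- matrix(as.numeric(presence > 0), nrow = P)
  inter <- tcrossprod(pres)               # |A intersect B|
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter  # |A union B|
  dis <- ifelse(un > 0, 1 - inter / un, 0)
  mean(dis[upper.tri(dis)])
}

#' Abundance-weighted geometric mean seed mass
#'
#' `exp(sum(w_s log SM_s))` with weights the regional abundance shares;
#' records which part of the seed-mass spectrum the surviving community
#' occupies.
#'
#' @param regional_abundance per-species regional abundances.
#' @param SM per-species seed masses (mg).
#' @return geometric mean seed mass (mg).
#' @export
weighted_geomean_sm <- function(regional_abundance, SM) {
  stopifnot(length(regional_abundance) == length(SM), all(SM > 0),
            all(regional_abundance >= 0))
  tot <- sum(regional_abundance)
  if (tot == 0) stop("empty community: no abundance to weight by")
  w <- regional_abundance / tot
  exp(sum(w[w > 0] * log(SM[w > 0])))
}

#' Climate-tracking lag of the warmest-adapted species
#'
#' For the `n_focal` surviving native species with the highest thermal
#' optima, the lag is the abundance-weighted mean temperature of the patches
#' a species occupies minus its optimum. A positive lag means the species
#' sits in sites warmer than its optimum, i.e. it failed to shift upslope
#' with its niche. Also returns the mean absolute lag and the Pearson
#' correlation of the absolute lag with seed mass.
#'
#' @param B patch x species biomass matrix (end of season).
#' @param T_patch per-patch current temperatures (degrees C).
#' @param traits `ms_traits` table.
#' @param natives integer ids of native species.
#' @param n_focal number of warmest-adapted natives to track (default 40).
#' @return list with `species_id`, `lag` (degrees C), `SM`, `mean_abs_lag`
#'   and `lag_sm_corr`.
#' @export
climate_lag <- function(B, T_patch, traits, natives, n_focal = 40) {
  reg <- colSums(B)
  alive <- intersect(natives, which(reg > 0))
  if (!length(alive))
    return(list(species_id = integer(0), lag = numeric(0), SM = numeric(0),
                mean_abs_lag = NA_real_, lag_sm_corr = NA_real_))
  focal <- alive[order(traits$T_opt[alive], decreasing = TRUE)]
  focal <- focal[seq_len(min(n_focal, length(focal)))]
  lag <- vapply(focal, function(s) {
    w <- B[, s] / reg[s]
    sum(w * T_patch) - traits$T_opt[s]
  }, numeric(1))
  sm <- traits$SM[focal]
  corr <- if (length(focal) >= 3 && stats::sd(abs(lag)) > 0 &&
              stats::sd(sm) > 0)
    stats::cor(abs(lag), sm) else NA_real_
  list(species_id = focal, lag = lag, SM = sm,
       mean_abs_lag = mean(abs(lag)), lag_sm_corr = corr)
}

#' Derive yearly events from consecutive presence matrices
#'
#' A colonisation is new establishment that persists through one growing
#' season: absent at the previous year's season end, present at this
#' year's. An exclusion is local loss of a species present the year before.
#'
#' @param prev,now patch x species logical presence matrices at the end of
#'   two consecutive growing seasons.
#' @return list of logical matrices `colonisations` and `exclusions`.
#' @export
presence_events <- function(prev, now) {
  list(colonisations = !prev & now, exclusions = prev & !now)
}

#' Colonisation and exclusion events per patch
#'
#' Sums event counts accumulated over the warming years, restricted to
#' native species, and divides by patch count.
#'
#' @param events list with patch x species count matrices `colonisations`
#'   and `exclusions` accumulated over the warming phase.
#' @param natives integer ids of native species.
#' @param n_patches number of patches.
#' @return list with `colonisations_per_patch` and `exclusions_per_patch`.
#' @export
count_events <- function(events, natives, n_patches) {
  list(
    colonisations_per_patch =
      sum(events$colonisations[, natives]) / n_patches,
    exclusions_per_patch = sum(events$exclusions[, natives]) / n_patches
  )
}

#' Percent change between two phases
#'
#' `100 * (after - before) / before`; the convention used for percent
#' extinctions (change in regional richness) and percent diversity change.
#'
#' @param before,after quantities in the same units; `before > 0`.
#' @return percent change.
#' @export
percent_change <- function(before, after) {
  if (before <= 0) stop("undefined change: 'before' must be positive")
  100 * (after - before) / before
}
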