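#' Two-dimensional exponential-power dispersal kernel
#'
#' Probability density (per m^2) of seed deposition at distance `d` from the
#' source: `c / (2 pi beta^2 Gamma(2/c)) * exp(-(d/beta)^c)`. The kernel is
#' Gaussian for `c = 2`, exponential for `c = 1` and leptokurtic (sharply
#' peaked with fat tails) for `c < 1`; the default shape used throughout the
#' simulator is `c = 0.5`.
#'
#' @param d distance from the source (m), >= 0.
#' @param beta kernel scale parameter (m), > 0.
#' @param c kernel shape parameter, > 0.
#' @return seed deposition density (1/m^2).
#' @examples
#' kernel_density(0, beta = 30, c = 0.5) # 0.5 / (2 * pi * 900 * 6)
#' @export
kernel_density <- function(d, beta, c = 0.5) {
  stopifnot(all(d >= 0), beta > 0, c > 0)
  c / (2 * pi * beta^2 * gamma(2 / c)) * exp(-(d / beta)^c)
}

#' Mean dispersal distance of the 2-D kernel
#'
#' The mean radial displacement is `beta * Gamma(3/c) / Gamma(2/c)`.
#'
#' @param beta kernel scale (m).
#' @param c kernel shape.
#' @return mean dispersal distance (m).
#' @examples
#' mean_dispersal_distance(30, 0.5) # 600
#' @export
mean_dispersal_distance <- function(beta, c = 0.5) {
  beta * gamma(3 / c) / gamma(2 / c)
}

#' Kernel scale from seed mass
#'
#' Mean dispersal distance decreases with seed mass as
#' `delta = a * SM^sm_exponent` (defaults `a = 600` m, exponent `-0.13`: a
#' 1 mg seed travels 600 m on average). Inverting the mean-distance relation
#' gives the species-specific scale
#' `beta = a * Gamma(2/c) / Gamma(3/c) * SM^sm_exponent`.
#'
#' @param SM seed mass (mg), > 0; may be a vector.
#' @param a distance-scaling constant (m) for a 1 mg seed.
#' @param c kernel shape.
#' @param sm_exponent exponent of the seed-mass scaling (negative: heavier
#'   seeds travel less far).
#' @return kernel scale(s) `beta` in m.
#' @examples
#' beta_from_sm(1) # 600 * gamma(4) / gamma(6) = 30
#' @export
beta_from_sm <- function(SM, a = 600, c = 0.5, sm_exponent = -0.13) {
  if (any(SM <= 0)) stop("invalid trait: seed mass must be positive")
  a * gamma(2 / c) / gamma(3 / c) * SM^sm_exponent
}

# Probability that a seed released at the centre of a patch lands within
# r_capture of it: the radial CDF of the 2-D kernel, integral_0^r 2 pi u
# P(u) du, by adaptive quadrature.
self_retention <- function(beta, c, r_capture) {
  vapply(beta, function(b) {
    stats::integrate(function(u) 2 * pi * u * kernel_density(u, b, c),
                     0, r_capture, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Per-species patch-to-patch dispersal matrices
#'
#' Discretises the continuous kernel onto the patch network. For source `i`
#' and target `j != i` the arrival probability is the kernel density at the
#' inter-patch distance times the capture area `pi * r_capture^2`; the
#' self-retention term `D[i, i]` is the exact radial integral of the kernel
#' over the capture disc. Rows whose discretised probabilities exceed 1 are
#' rescaled proportionally (with a warning); in an open landscape row sums
#' are otherwise < 1 and the remainder is seed loss across the boundary.
#'
#' @param landscape an `ms_landscape` object.
#' @param beta numeric vector of per-species kernel scales (m).
#' @param c kernel shape.
#' @param r_capture patch seed-capture radius (m).
#' @return numeric array `[source, target, species]` of arrival
#'   probabilities.
#' @export
build_dispersal_matrix <- function(landscape, beta, c = 0.5,
                                   r_capture = 50) {
  stopifnot(all(beta > 0), r_capture > 0)
  P <- nrow(landscape$patches)
  S <- length(beta)
  area <- pi * r_capture^2
  D <- array(0, dim = c(P, P, S))
  retain <- self_retention(beta, c, r_capture)
  for (s in seq_len(S)) {
    M <- kernel_density(landscape$dist_m, beta[s], c) * area
    diag(M) <- retain[s]
    rs <- rowSums(M)
    over <- rs > 1
    if (any(over)) {
      warning("capture discs overlap: rescaling ", sum(over),
              " dispersal rows to unit mass")
      M[over, ] <- M[over, , drop = FALSE] / rs[over]
    }
    D[, , s] <- M
  }
  D
}

#' Seed production from end-of-season biomass
#'
#' Seeds (continuous-valued) are produced in proportion to local biomass:
#' `seeds = fecundity * B_end`, per patch and species.
#'
#' @param B_end patch x species end-of-season biomass matrix.
#' @param fecundity per-species seeds per unit biomass.
#' @return patch x species seed-output matrix.
#' @export
produce_seeds <- function(B_end, fecundity) {
  stopifnot(ncol(B_end) == length(fecundity), all(B_end >= 0))
  B_end * rep(fecundity, each = nrow(B_end))
}

#' Disperse seeds and convert germinants to next year's starting biomass
#'
#' Applies the deterministic dispersal map (`arriving[j, s] = sum_i
#' seeds[i, s] * D[i, j, s]`), then germination and seedling conversion:
#' `B_start = arriving * germ_p * seedling_b`. All adults die after seed
#' dispersal and non-germinating seeds are discarded (annuals, no seed
#' bank), so the result fully replaces the previous biomass.
#'
#' @param seeds patch x species seed-output matrix.
#' @param D dispersal array from [build_dispersal_matrix()].
#' @param germ_p per-species germination probabilities.
#' @param seedling_b per-species seedling biomass.
#' @param extra_seeds optional patch x species matrix of seed input arriving
#'   from outside the landscape (regional-pool immigration), already
#'   expressed as seeds arriving in each patch.
#' @return patch x species starting-biomass matrix for the next year.
#' @export
disperse_and_establish <- function(seeds, D, germ_p, seedling_b,
                                   extra_seeds = NULL) {
  if (!is.array(D) || length(dim(D)) != 3 ||
      any(dim(D) != c(nrow(seeds), nrow(seeds), ncol(seeds))))
    stop("dispersal array dimensions do not conform to the seed matrix")
  arriving <- cpp_disperse(seeds, D)
  if (!is.null(extra_seeds)) arriving <- arriving + extra_seeds
  arriving * rep(germ_p * seedling_b, each = nrow(seeds))
}
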