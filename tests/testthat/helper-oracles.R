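# Shared oracles and fixture builders. Oracles deliberately re-derive
# quantities from their definitions (explicit loops, quadrature, closed
# forms) independently of the package's vectorised implementations.

# Reduced-size configuration used by the property suite.
small_config <- function(...) {
  ms_config(n_species = 60, n_patches = 25, n_replicates = 5, ...)
}

# Explicit double-loop Lotka-Volterra daily step with a full alpha matrix
# (alpha_ii = 1 on the diagonal).
lv_day_step_oracle <- function(B, r, K, alpha_mat, m) {
  S <- length(B)
  out <- numeric(S)
  for (i in seq_len(S)) {
    interact <- 0
    for (j in seq_len(S)) if (j != i) {
      interact <- interact + alpha_mat[i, j] * B[j] / K[j]
    }
    out[i] <- B[i] + r[i] * (1 - B[i] / K[i] - interact) * B[i] - m * B[i]
  }
  pmax(out, 0)
}

# Radial integral of the 2-D exponential-power kernel by quadrature.
kernel_radial_integral <- function(beta, c, f = function(d) 1,
                                   upper = Inf) {
  stats::integrate(function(d) f(d) * 2 * pi * d * kernel_density(d, beta, c),
                   0, upper, rel.tol = 1e-10)$value
}

# Closed-form radial CDF of the c = 1/2 kernel at radius r:
# F(r) = 1 - exp(-s) (s^3/6 + s^2/2 + s + 1), s = sqrt(r / beta).
retention_closed_form <- function(beta, r_capture) {
  s <- sqrt(r_capture / beta)
  1 - exp(-s) * (s^3 / 6 + s^2 / 2 + s + 1)
}

# Brute-force inverse-Simpson diversity partition from the definitions.
diversity_oracle <- function(B) {
  inv <- function(x) {
    p <- x / sum(x)
    1 / sum(p^2)
  }
  occ <- which(rowSums(B) > 0)
  alphas <- vapply(occ, function(p) inv(B[p, ]), numeric(1))
  alpha <- mean(alphas)
  gamma <- inv(colSums(B))
  list(alpha = alpha, beta = gamma / alpha, gamma = gamma)
}

# OLS prediction via explicit normal equations.
ols_predict_oracle <- function(x, y, x0) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(beta[1] + beta[2] * x0)
}
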