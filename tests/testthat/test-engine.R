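test_that("initialisation populates every patch with every species equally", {
  cfg <- small_config()
  set.seed(61)
  run <- initialize_run(cfg)
  expect_equal(dim(run$B), c(25, 60))
  expect_true(all(run$B == cfg$K_max / (2 * cfg$n_species)))
  expect_true(all(run$B > 0))
  set.seed(61); run2 <- initialize_run(cfg)
  expect_identical(run[c("B", "traits")], run2[c("B", "traits")])
})

test_that("one simulated year matches an independent straight-line trace", {
  cfg <- ms_config(n_species = 2, n_patches = 2, pool_enabled = FALSE)
  set.seed(62)
  run <- initialize_run(cfg)
  B <- matrix(runif(4, 1, 40), 2, 2)
  T_patch <- run$landscape$patches$T_base
  got <- step_year(B, T_patch, run, cfg)

  # independent re-implementation of the yearly loop
  tr <- run$traits
  r <- K <- matrix(0, 2, 2)
  for (p in 1:2) for (s in 1:2) {
    r[p, s] <- cfg$r_max *
      exp(-(T_patch[p] - tr$T_opt[s])^2 / (2 * cfg$sigma_opt^2))
    K[p, s] <- max(cfg$K_max * r[p, s] / cfg$r_max,
                   cfg$K_floor_frac * cfg$K_max)
  }
  Bm <- B
  amat <- matrix(cfg$alpha, 2, 2); diag(amat) <- 1
  for (d in 1:120) for (p in 1:2)
    Bm[p, ] <- lv_day_step_oracle(Bm[p, ], r[p, ], K[p, ], amat, cfg$m)
  Bm[Bm < cfg$extinction_threshold] <- 0
  seeds <- Bm * rep(tr$fecundity, each = 2)
  arr <- matrix(0, 2, 2)
  for (s in 1:2) for (j in 1:2) for (i in 1:2)
    arr[j, s] <- arr[j, s] + seeds[i, s] * run$D[i, j, s]
  Bn <- arr * rep(tr$germ_p * tr$seedling_b, each = 2)

  expect_equal(got$B_end, Bm, tolerance = 1e-12)
  expect_equal(got$B_next, Bn, tolerance = 1e-12)
})

test_that("an empty metacommunity without pool input stays empty", {
  cfg <- ms_config(n_species = 3, n_patches = 3, pool_enabled = FALSE)
  set.seed(63)
  run <- initialize_run(cfg)
  st <- step_year(matrix(0, 3, 3), run$landscape$patches$T_base, run, cfg)
  expect_equal(st$B_end, matrix(0, 3, 3))
  expect_equal(st$B_next, matrix(0, 3, 3))
})

test_that("stable phase converges to a fixed point without competition", {
  cfg <- ms_config(n_species = 2, n_patches = 5, alpha = 0,
                   pool_enabled = FALSE, native_threshold = 1)
  set.seed(64)
  run <- initialize_run(cfg)
  stable <- run_stable_phase(run, cfg)
  expect_true(stable$converged)
  # a further year changes essentially nothing
  st <- step_year(stable$B, run$landscape$patches$T_base, run, cfg)
  expect_lt(max(abs(st$B_end - stable$B_end)) / max(stable$B_end), 1e-3)
  expect_setequal(stable$natives, 1:2)
  # unattainable tolerance cannot converge
  cfg0 <- ms_config(n_species = 2, n_patches = 5, alpha = 0,
                    pool_enabled = FALSE, stable_tol = 0,
                    max_stable_years = 25)
  set.seed(64); run0 <- initialize_run(cfg0)
  expect_warning(st0 <- run_stable_phase(run0, cfg0), "did not converge")
  expect_false(st0$converged)
})

test_that("simulations are bit-reproducible and replicate bookkeeping is sound", {
  cfg <- ms_config(n_species = 20, n_patches = 10, max_stable_years = 80,
                   settling_years = 10, native_threshold = 1,
                   n_replicates = 1, base_seed = 7)
  a <- suppressWarnings(metacommunity_sim(cfg, seed = 3))
  b <- suppressWarnings(metacommunity_sim(cfg, seed = 3))
  expect_identical(a$stable$B_end, b$stable$B_end)
  expect_identical(a$post$B_end, b$post$B_end)
  expect_identical(summary(a), summary(b))

  ens1 <- suppressWarnings(run_replicates(cfg))
  ens2 <- suppressWarnings(run_replicates(cfg))
  expect_identical(ens1$summary, ens2$summary)
  # a single replicate's mean is the replicate itself
  expect_equal(unname(ens1$mean["pct_change_richness"]),
               ens1$summary$pct_change_richness[1])
  expect_equal(ens1$summary$seed, cfg$base_seed + 1)
})

test_that("patch temperatures rise by exactly the forcing total", {
  cfg <- ms_config(n_species = 12, n_patches = 8, max_stable_years = 60,
                   settling_years = 5, native_threshold = 1)
  sim <- suppressWarnings(metacommunity_sim(cfg, seed = 9))
  expect_equal(sim$post$T_patch - sim$landscape$patches$T_base,
               rep(cfg$warming_C, 8))
  # native-filtered accounting: richness can only be lost
  expect_lte(sim$post$regional_richness, sim$stable$regional_richness)
  # beta = gamma/alpha holds in every emitted summary
  expect_equal(sim$stable$beta_div,
               sim$stable$gamma_div / sim$stable$alpha_div)
  expect_equal(sim$post$beta_div, sim$post$gamma_div / sim$post$alpha_div)
})
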