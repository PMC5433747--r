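test_that("Gaussian growth rate behaves at and away from the optimum", {
  expect_equal(growth_rate(10, 10, r_max = 0.05), 0.05)
  expect_equal(growth_rate(13, 10, r_max = 0.05, sigma_opt = 3),
               0.05 * exp(-0.5))
  # symmetry and monotone decay in |T - T_opt|
  expect_equal(growth_rate(8, 10), growth_rate(12, 10))
  r <- growth_rate(10 + 0:8, 10)
  expect_true(all(diff(r) < 0))
  expect_lt(growth_rate(40, 10), 1e-10)
})

test_that("carrying capacity is proportional to growth rate with a floor", {
  expect_equal(carrying_capacity(10, 10, K_max = 100), 100)
  r1 <- growth_rate(11, 10); r2 <- growth_rate(13, 10)
  expect_equal(carrying_capacity(11, 10) / carrying_capacity(13, 10),
               r1 / r2)
  # at |dT| = 6 sigma the raw proportional value sinks below the floor
  K_far <- carrying_capacity(10 + 18, 10, sigma_opt = 3, K_max = 100,
                             K_floor = 1e-2)
  expect_equal(K_far, 1e-2)
  expect_lt(100 * exp(-18), 1e-2)
})

test_that("single-species dynamics match the logistic fixed points", {
  # B = K with no mortality is an equilibrium
  expect_equal(lv_day_step(50, 0.05, 50, alpha = 0.5, m = 0), 50)
  # near-zero biomass grows at about (r - m) B
  d <- lv_day_step(1e-8, 0.05, 100, alpha = 0, m = 0.001) - 1e-8
  expect_equal(d, (0.05 - 0.001) * 1e-8, tolerance = 1e-6)
  # logistic-with-mortality fixed point B* = K (1 - m/r)
  B <- 1
  for (i in 1:5000) B <- lv_day_step(B, 0.05, 100, alpha = 0, m = 0.001)
  expect_equal(B, 100 * (1 - 0.001 / 0.05), tolerance = 1e-8)
})

test_that("two identical competitors settle at K / (1 + alpha)", {
  B <- c(5, 5)
  for (i in 1:5000)
    B <- lv_day_step(B, c(0.05, 0.05), c(80, 80), alpha = 0.5, m = 0)
  expect_equal(B, rep(80 / 1.5, 2), tolerance = 1e-8)
})

test_that("equal-alpha shortcut agrees with the double-loop oracle", {
  set.seed(21)
  for (case in 1:5) {
    S <- 10
    B <- runif(S, 0, 50)
    r <- runif(S, 0.01, 0.06)
    K <- runif(S, 20, 100)
    alpha <- runif(1, 0, 0.9)
    amat <- matrix(alpha, S, S); diag(amat) <- 1
    expect_equal(lv_day_step(B, r, K, alpha, m = 0.001),
                 lv_day_step_oracle(B, r, K, amat, m = 0.001),
                 tolerance = 1e-12)
  }
})

test_that("growing season runs 120 daily updates and preserves non-negativity", {
  set.seed(22)
  P <- 4; S <- 6
  B <- matrix(runif(P * S, 0, 30), P, S)
  r <- matrix(runif(P * S, 0.01, 0.06), P, S)
  K <- matrix(runif(P * S, 10, 100), P, S)
  out <- run_growing_season(B, r, K, alpha = 0.4, m = 0.001,
                            extinction_threshold = 1e-9)
  # replicate by applying the daily step patch-wise 120 times
  man <- B
  for (d in 1:120) for (p in 1:P)
    man[p, ] <- lv_day_step(man[p, ], r[p, ], K[p, ], 0.4, 0.001)
  man[man < 1e-9] <- 0
  expect_equal(out, man, tolerance = 1e-12)
  expect_true(all(out >= 0))
  expect_false(any(!is.finite(out)))
  # all-zero input is absorbing
  expect_equal(run_growing_season(matrix(0, P, S), r, K, 0.4), matrix(0, P, S))
})

test_that("without interspecific competition species are independent", {
  set.seed(23)
  B <- matrix(runif(12, 1, 20), 2, 6)
  r <- matrix(0.04, 2, 6)
  K <- matrix(runif(12, 30, 90), 2, 6)
  perm <- sample(6)
  full <- run_growing_season(B, r, K, alpha = 0, m = 0.001)
  permed <- run_growing_season(B[, perm], r[, perm], K[, perm],
                               alpha = 0, m = 0.001)
  expect_equal(full[, perm], permed, tolerance = 1e-14)
  # with alpha = 0 each species converges toward K (1 - m/r)
  Bc <- matrix(10, 1, 3)
  rc <- matrix(0.05, 1, 3)
  Kc <- matrix(c(40, 60, 80), 1, 3)
  for (i in 1:60) Bc <- run_growing_season(Bc, rc, Kc, alpha = 0, m = 0.001)
  expect_equal(as.numeric(Bc), c(40, 60, 80) * (1 - 0.001 / 0.05),
               tolerance = 1e-6)
})
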