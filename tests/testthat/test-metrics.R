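test_that("inverse Simpson equals effective species number", {
  expect_equal(inverse_simpson(rep(2.5, 7)), 7)
  expect_equal(inverse_simpson(c(0, 5, 0)), 1)
  expect_equal(inverse_simpson(c(0.7, 0.3)), 1 / (0.49 + 0.09))
  expect_equal(inverse_simpson(numeric(3)), 0)  # empty-community sentinel
  expect_error(inverse_simpson(c(-1, 2)))
})

test_that("diversity partition satisfies beta = gamma/alpha and matches brute force", {
  # identical patches: beta = 1
  B <- matrix(rep(c(3, 1, 6), each = 4), 4, 3)
  d <- diversity_partition(B)
  expect_equal(d$beta, 1)
  # monodominant distinct species per patch: alpha 1, gamma = beta = n
  M <- diag(c(2, 2, 2, 2))
  d2 <- diversity_partition(M)
  expect_equal(d2$alpha, 1)
  expect_equal(d2$gamma, 4)
  expect_equal(d2$beta, 4)
  # random matrices against the brute-force oracle
  set.seed(51)
  for (i in 1:5) {
    R <- matrix(rexp(24), 4, 6)
    R[sample(24, 6)] <- 0
    got <- diversity_partition(R)
    want <- diversity_oracle(R)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
    expect_equal(got$beta, want$beta, tolerance = 1e-12)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-12)
  }
  expect_equal(diversity_partition(matrix(0, 2, 2)),
               list(alpha = 0, beta = 0, gamma = 0))
})

test_that("Jaccard dissimilarity handles identity, disjointness and overlap", {
  expect_equal(jaccard_mean(rbind(c(1, 1, 0), c(1, 1, 0))), 0)
  expect_equal(jaccard_mean(rbind(c(1, 0), c(0, 1))), 1)
  # {A,B} vs {B,C}: 1 - 1/3
  expect_equal(jaccard_mean(rbind(c(1, 1, 0), c(0, 1, 1))), 2 / 3)
  # both-empty pairs contribute 0
  expect_equal(jaccard_mean(rbind(c(0, 0), c(0, 0), c(1, 0))), 2 / 3)
})

test_that("abundance-weighted geometric mean seed mass", {
  expect_equal(weighted_geomean_sm(c(1, 1), c(1, 4)), 2)
  expect_equal(weighted_geomean_sm(c(0, 3), c(1.2, 7.7)), 7.7)
  expect_equal(weighted_geomean_sm(c(0.8, 0.2), c(1, 4)), exp(0.2 * log(4)))
  expect_error(weighted_geomean_sm(c(0, 0), c(1, 2)), "empty")
})

test_that("climate lag and its seed-mass correlation match hand computation", {
  # 3 species, 2 patches at 12 and 14 degC
  traits <- data.frame(T_opt = c(13, 14, 15), SM = c(0.5, 2, 8))
  B <- rbind(c(2, 1, 0),
             c(2, 3, 4))
  T_patch <- c(12, 14)
  lag <- climate_lag(B, T_patch, traits, natives = 1:3, n_focal = 3)
  # hand: weighted mean T per species minus optimum
  hand <- c((2 * 12 + 2 * 14) / 4 - 13, (1 * 12 + 3 * 14) / 4 - 14, 14 - 15)
  expect_equal(lag$lag[order(lag$species_id)], hand, tolerance = 1e-10)
  expect_equal(lag$mean_abs_lag, mean(abs(hand)), tolerance = 1e-10)
  expect_equal(lag$lag_sm_corr, cor(abs(hand), traits$SM), tolerance = 1e-10)
  # species sitting exactly at its optimum has zero lag
  lag0 <- climate_lag(rbind(c(1, 0, 0), c(0, 0, 0)), c(13, 14), traits, 1:3)
  expect_equal(lag0$lag[lag0$species_id == 1], 0)
  # focal set restricted to the warmest natives
  lagf <- climate_lag(B, T_patch, traits, natives = 1:3, n_focal = 2)
  expect_setequal(lagf$species_id, 2:3)
  # regionally extinct natives are excluded
  lage <- climate_lag(cbind(B[, 1:2], 0), T_patch, traits, 1:3, n_focal = 3)
  expect_false(3 %in% lage$species_id)
})

test_that("event counting matches a brute-force recount of presence changes", {
  set.seed(52)
  series <- lapply(1:6, function(i) matrix(runif(20) > 0.5, 4, 5))
  col <- exc <- matrix(0, 4, 5)
  for (t in 2:6) {
    ev <- presence_events(series[[t - 1]], series[[t]])
    col <- col + ev$colonisations
    exc <- exc + ev$exclusions
  }
  # brute force from the definitions
  bc <- be <- 0
  natives <- c(1, 2, 4)
  for (t in 2:6) for (p in 1:4) for (s in natives) {
    if (!series[[t - 1]][p, s] && series[[t]][p, s]) bc <- bc + 1
    if (series[[t - 1]][p, s] && !series[[t]][p, s]) be <- be + 1
  }
  got <- count_events(list(colonisations = col, exclusions = exc),
                      natives, n_patches = 4)
  expect_equal(got$colonisations_per_patch, bc / 4)
  expect_equal(got$exclusions_per_patch, be / 4)
  # no changes, no events
  same <- presence_events(series[[1]], series[[1]])
  expect_equal(sum(same$colonisations) + sum(same$exclusions), 0)
})

test_that("percent change follows the extinction-percent convention", {
  expect_equal(percent_change(120, 120), 0)
  expect_equal(percent_change(100, 61), -39)
  expect_equal(percent_change(70.9, 57.4), 100 * (57.4 - 70.9) / 70.9)
  expect_error(percent_change(0, 5), "positive")
})
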