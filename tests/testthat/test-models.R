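test_that("kernels reproduce LINE4 hand arithmetic", {
  # intervention: p = m n / ((m+s)(m+n+s))
  expect_equal(intervention_kernel(10, 20, 0), 200 / 300)
  expect_equal(intervention_kernel(10, 40, 50), 400 / 6000)
  expect_equal(intervention_kernel(10, 0, 5), 0)
  expect_equal(intervention_kernel(0, 0, 0), 0) # all-zero corner: 0 by convention
  # competition: q = n m / ((n+s)(n+m+s)), circle centred at the destination
  expect_equal(competition_kernel(20, 10, 0), 200 / 600)
  expect_equal(competition_kernel(20, 40, 40), 800 / 6000)
  expect_equal(competition_kernel(20, 0, 40), 0)
})

test_that("original radiation prediction and telescoping row sums (LINE4)", {
  fx <- line4()
  Ti <- c(100, 0, 0, 0)
  rad <- predict_radiation(fx$system, fx$s, Ti)
  expect_equal(unname(rad["L0", c("L1", "L2", "L3")]),
               c(200 / 3, 100 / 6, 20 / 3), tolerance = 1e-12)
  expect_equal(sum(rad["L0", ]), 100 * (1 - 10 / 100)) # 1 - m_i/M telescoping
  expect_equal(unname(rad["L1", ]), rep(0, 4))         # zero T_i, zero row
})

test_that("telescoping identities hold on random systems (both kernels)", {
  for (seed in 1:25) {
    sys <- random_system(40, 1000 + seed)
    d <- pairwise_distances(sys)
    s <- intervening_population(sys, d)
    P <- kernel_matrix(sys, s, "intervention")
    Q <- kernel_matrix(sys, s, "competition")
    m <- sys$population
    expect_true(max(abs(rowSums(P) - (1 - m / sys$M))) < 1e-9,
                label = sprintf("intervention telescoping, seed %d", seed))
    expect_true(max(abs(colSums(Q) - (1 - m / sys$M))) < 1e-9,
                label = sprintf("competition telescoping, seed %d", seed))
  }
})

test_that("PIR generalized prediction matches LINE4 shares", {
  fx <- line4()
  obs <- zero_flux(fx$system)
  obs["L0", "L1"] <- 100 # carrier of T_0 = 100
  run <- function(lambda) {
    spec <- model_spec("PIR", lambda = lambda, kappa = 1)
    unclass(predict_generalized(fx$system, fx$s, spec, flux_matrix(obs)))
  }
  expect_equal(unname(run(1)["L0", -1]), c(2000, 500, 200) / 27,
               tolerance = 1e-6) # 74.074 / 18.519 / 7.407
  expect_equal(unname(run(0)["L0", -1]), rep(100 / 3, 3)) # uniform limit
  expect_equal(unname(run(0.5)["L0", -1]), c(55.0592, 27.5296, 17.4112),
               tolerance = 1e-5)
})

test_that("PCR reads Table-1 cell verbatim: s centred at candidates (LINE4 pin)", {
  fx <- line4()
  obs <- zero_flux(fx$system)
  obs["L0", "L1"] <- 100
  spec <- model_spec("PCR", lambda = 1, kappa = 1)
  pcr <- predict_generalized(fx$system, fx$s, spec, flux_matrix(obs))
  # q(L0->L1,L2,L3) = 1/3, 1/30, 2/45 -> shares 30/37, 3/37, 4/37 of T_0
  expect_equal(unname(unclass(pcr)["L0", -1]), c(3000, 300, 400) / 37,
               tolerance = 1e-9)
})

test_that("marginal conservation across variants and lambdas", {
  sys <- random_system(30, 7)
  d <- pairwise_distances(sys)
  s <- intervening_population(sys, d)
  obs <- sample_flows(sys, s, "PIR", 0.5, trips_per_origin = 500, seed = 8)
  Ti <- production_totals(obs)
  Tj <- attraction_totals(obs)
  for (lam in c(0, 0.3, 0.7, 1)) {
    for (v in c("PIR", "PCR")) {
      pred <- predict_generalized(sys, s, model_spec(v, lam), obs)
      kap <- attr(pred, "kappa")
      expect_lt(max(abs(rowSums(unclass(pred)) - kap * Ti) /
                      pmax(kap * Ti, 1e-12)), 1e-9)
    }
    for (v in c("AIR", "ACR")) {
      pred <- predict_generalized(sys, s, model_spec(v, lam), obs)
      kap <- attr(pred, "kappa")
      expect_lt(max(abs(colSums(unclass(pred)) - kap * Tj) /
                      pmax(kap * Tj, 1e-12)), 1e-9)
    }
  }
})

test_that("PIR at lambda 1 equals the finite-size-normalized radiation model", {
  for (seed in c(3, 14, 25)) {
    sys <- random_system(35, seed)
    d <- pairwise_distances(sys)
    s <- intervening_population(sys, d)
    obs <- sample_flows(sys, s, "PIR", 1, trips_per_origin = 1000, seed = seed)
    spec <- model_spec("PIR", lambda = 1, kappa_support = "all_pairs")
    pir <- predict_generalized(sys, s, spec, obs)
    # normalized radiation: T_i p_ij / (1 - m_i / M)
    P <- kernel_matrix(sys, s, "intervention")
    norm_rad <- production_totals(obs) * P / (1 - sys$population / sys$M)
    expect_lt(max(abs(unclass(pir) - norm_rad)), 1e-9)
    expect_equal(attr(pir, "kappa"), 1, tolerance = 1e-12)
  }
})

test_that("scale covariance: c times the observed trips scales predictions by c", {
  fx <- line4()
  obs <- zero_flux(fx$system)
  obs["L0", "L1"] <- 30; obs["L1", "L2"] <- 20; obs["L2", "L3"] <- 50
  obs <- flux_matrix(obs)
  for (v in c("PIR", "ACR")) {
    spec <- model_spec(v, lambda = 0.7)
    p1 <- predict_generalized(fx$system, fx$s, spec, obs)
    p3 <- predict_generalized(fx$system, fx$s, spec, flux_matrix(unclass(obs) * 3))
    expect_equal(unclass(p3), unclass(p1) * 3,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("kappa: identity, observed-pairs restriction, undefined cases", {
  fx <- line4()
  obs <- zero_flux(fx$system)
  obs["L0", "L1"] <- 100
  spec <- model_spec("PIR", lambda = 1, kappa = 1)
  unscaled <- unclass(predict_generalized(fx$system, fx$s, spec,
                                          flux_matrix(obs)))
  expect_equal(compute_kappa(unscaled, unscaled, "all_pairs"), 1)
  target <- zero_flux(fx$system)
  target["L0", "L1"] <- 50
  expect_equal(compute_kappa(unscaled, target, "observed_pairs"),
               50 / (2000 / 27), tolerance = 1e-9) # 0.675
  empty_overlap <- zero_flux(fx$system)
  empty_overlap["L1", "L0"] <- 5 # prediction is zero there (T_1 = 0)
  expect_error(compute_kappa(unscaled, empty_overlap, "observed_pairs"),
               class = "radflux_undefined_kappa")
})

test_that("predictions are nonnegative with zero diagonal; bad allocations error", {
  sys <- random_system(20, 31)
  d <- pairwise_distances(sys)
  s <- intervening_population(sys, d)
  obs <- sample_flows(sys, s, "ACR", 0.8, trips_per_origin = 300, seed = 32)
  for (v in c("PIR", "PCR", "AIR", "ACR")) {
    pred <- unclass(predict_generalized(sys, s, model_spec(v, 0.8), obs))
    expect_true(all(pred >= 0))
    expect_true(all(diag(pred) == 0))
  }
  # zero-population system: kernel weights vanish but trips are demanded
  zs <- build_system(data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0,
                                population = c(0, 0, 0)))
  zd <- pairwise_distances(zs)
  zsij <- intervening_population(zs, zd)
  zobs <- flux_matrix(matrix(c(0, 0, 0, 5, 0, 0, 0, 0, 0), 3, 3,
                             dimnames = list(zs$id, zs$id)))
  expect_error(predict_generalized(zs, zsij, model_spec("PIR", 1), zobs),
               class = "radflux_undefined_allocation")
})

test_that("gravity baseline: no-deterrence shares, beta = 1, strong decay limit", {
  fx <- line4()
  Ti <- c(100, 0, 0, 0)
  g0 <- gravity_baseline(fx$system, fx$dist, Ti, beta = 0)
  expect_equal(unname(unclass(g0)["L0", -1]), c(200, 300, 400) / 9,
               tolerance = 1e-9) # shares prop. to n_j
  g1 <- gravity_baseline(fx$system, fx$dist, Ti, beta = 1)
  w <- c(20, 15, 40 / 3)
  expect_equal(unname(unclass(g1)["L0", -1]), 100 * w / sum(w),
               tolerance = 1e-9) # 41.38 / 31.03 / 27.59
  gBig <- gravity_baseline(fx$system, fx$dist, Ti, beta = 50)
  expect_gt(unclass(gBig)["L0", "L1"], 99.999) # all flux to the nearest
  dup <- build_system(data.frame(id = c("A", "B", "C"), x = c(0, 0, 1), y = 0,
                                 population = 1))
  expect_error(gravity_baseline(dup, pairwise_distances(dup), c(1, 1, 1), 2),
               class = "radflux_undefined_deterrence")
})
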