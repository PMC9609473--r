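test_that("conversion profile obeys the closed-form limits", {
  kc <- rate_constants(ref_pair["k1"], ref_pair["k_minus1"])
  expect_equal(conversion_profile(kc, 0), 0)
  # algebraic limit: xi -> K/(1+K)
  xi_inf <- kc$K / (1 + kc$K)
  expect_equal(conversion_profile(kc, 1e6), xi_inf, tolerance = 1e-12)
  expect_equal(xi_inf, 0.09734513, tolerance = 1e-7)
  # value at 5 h, frozen from the independent ODE integration
  expect_equal(conversion_profile(kc, 5), 0.05563422, tolerance = 1e-7)
  # monotone, strictly below the asymptote at finite times
  tt <- seq(0, 100, 0.5)
  xi <- conversion_profile(kc, tt)
  expect_true(all(diff(xi) > 0))
  expect_true(all(xi < xi_inf))
  expect_error(conversion_profile(kc, c(1, -2)), "negative")
})

test_that("equilibrium constant maps xi_inf <-> K consistently", {
  expect_equal(equilibrium_constant(0.5), 1)
  expect_equal(equilibrium_constant(2 / 3), 2, tolerance = 1e-12)
  expect_equal(equilibrium_constant(0.09733), 0.107822,
               tolerance = 1e-4)
  expect_error(equilibrium_constant(0), "0, 1")
  expect_error(equilibrium_constant(1), "0, 1")
  # inverse consistency over a log grid of K
  K <- 10^seq(-3, 3, length.out = 25)
  expect_equal(equilibrium_constant(K / (1 + K)), K, tolerance = 1e-9)
  expect_true(all(diff(equilibrium_constant(seq(0.01, 0.99, 0.01))) > 0))
})

test_that("splitting the summed constant recovers the pair", {
  s <- split_rate_constants(0.2, 1)
  expect_equal(c(s$k1, s$k_minus1), c(0.1, 0.1))
  # reproduces the published 310 K / pH 7 pair from (k, K)
  s <- split_rate_constants(0.1695, 0.0165 / 0.153)
  expect_equal(s$k1, 0.0165, tolerance = 1e-12)
  expect_equal(s$k_minus1, 0.153, tolerance = 1e-12)
  # K = 0: nothing released at equilibrium
  s0 <- split_rate_constants(0.3, 0)
  expect_equal(c(s0$k1, s0$k_minus1), c(0, 0.3))
  expect_error(split_rate_constants(-1, 1), "> 0")
  expect_error(split_rate_constants(0.1, -2), ">= 0")
  # round trip across random pairs
  pairs <- random_pairs(50, seed = 11)
  for (i in seq_len(nrow(pairs))) {
    k1 <- pairs[i, 1]; km1 <- pairs[i, 2]
    s <- split_rate_constants(k1 + km1, k1 / km1)
    expect_lt(abs(s$k1 - k1) / k1, 1e-12)
    expect_lt(abs(s$k_minus1 - km1) / km1, 1e-12)
    expect_equal(s$k_total, k1 + km1, tolerance = 1e-14)
  }
})

test_that("rate_constants enforces its internal identities", {
  kc <- rate_constants(0.0165, 0.153)
  expect_equal(kc$k_total, kc$k1 + kc$k_minus1)
  expect_equal(kc$K * kc$k_minus1, kc$k1, tolerance = 1e-12)
  expect_error(rate_constants(-0.1, 0.2), ">= 0")
})

test_that("carboxyl concentration and the normalised binding constant", {
  cond <- experiment_condition(310, 7, x_aa = 0.039,
                               copolymer_conc = 1e-2)
  cc <- cooh_concentration(cond)
  # hand calculation with repeat-unit masses 72.06 / 111.14 g/mol
  expect_equal(cc, 3.557879e-3, tolerance = 1e-6)
  expect_equal(normalized_binding_constant(0.153, cc), 43.0,
               tolerance = 1e-3)
  expect_equal(normalized_binding_constant(0, cc), 0)
  # proportionality: doubling the concentration halves k-1'
  cond2 <- experiment_condition(310, 7, 0.039, 2e-2)
  expect_equal(normalized_binding_constant(0.153,
                                           cooh_concentration(cond2)),
               43.0 / 2, tolerance = 1e-3)
  expect_equal(
    cooh_concentration(experiment_condition(310, 7, 0, 1e-2)), 0)
  # linear in copolymer concentration at fixed composition
  concs <- c(1e-3, 2e-3, 4e-3)
  ccs <- vapply(concs, function(cv)
    cooh_concentration(experiment_condition(310, 7, 0.039, cv)),
    numeric(1))
  expect_equal(ccs / concs, rep(ccs[1] / concs[1], 3), tolerance = 1e-12)
  expect_error(normalized_binding_constant(0.1, 0), "> 0")
})

test_that("ODE integration matches the closed form and conserves mass", {
  # frozen constants: integrator agrees with the analytic profile
  times <- seq(0, 48, 2)
  pairs <- random_pairs(50, seed = 3)
  for (i in seq_len(nrow(pairs))) {
    kc <- rate_constants(pairs[i, 1], pairs[i, 2])
    sol <- ode_release(kc, c_max = 1, times = times)
    cf <- conversion_profile(kc, times)
    expect_lt(max_rel_diff(sol$conversion, cf, floor = 1e-8), 1e-8)
    expect_lt(max(abs(sol$c_free + sol$c_bound - 1)), 1e-9)
  }
  # zero rates: state constant in time
  still <- ode_release(rate_constants(0, 0), 2, times)
  expect_equal(still$c_free, rep(0, length(times)))
  expect_equal(still$c_bound, rep(2, length(times)))
  # steady state satisfies k1 * c_bound = k-1 * c_free
  kc <- rate_constants(0.12, 0.08)
  ss <- ode_release(kc, 1, c(0, 500))
  expect_equal(kc$k1 * ss$c_bound[2], kc$k_minus1 * ss$c_free[2],
               tolerance = 1e-6)
  expect_error(ode_release(kc, -1, times), "> 0")
})
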