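noiseless_curve <- function(k1, km1, times = seq(0, 48, 2)) {
  simulate_release(synthetic_spec(rate_constants(k1, km1), times = times,
                                  noise_sd = 0))
}

test_that("equilibrium conversion is recovered from clean and noisy data", {
  cur <- noiseless_curve(ref_pair["k1"], ref_pair["k_minus1"])
  est <- estimate_equilibrium_conversion(cur)
  expect_equal(est$xi_inf, 0.0165 / 0.1695, tolerance = 1e-6)
  # a flat curve is its own plateau
  flat <- release_curve(0:9, rep(0.42, 10))
  expect_equal(
    estimate_equilibrium_conversion(flat, method = "plateau")$xi_inf,
    0.42)
  # noisy curve: within 5% of truth
  noisy <- simulate_release(synthetic_spec(
    rate_constants(ref_pair["k1"], ref_pair["k_minus1"]),
    noise_sd = 0.002, seed = 7))
  est_n <- estimate_equilibrium_conversion(noisy)
  expect_lt(abs(est_n$xi_inf - 0.0165 / 0.1695) / (0.0165 / 0.1695),
            0.05)
  # a curve stopped far short of its plateau gets flagged, not failed
  early <- noiseless_curve(0.0165, 0.153, times = seq(0, 4, 0.5))
  est_e <- estimate_equilibrium_conversion(early, method = "plateau")
  expect_true(length(est_e$warnings) > 0)
})

test_that("semilog linearization reproduces slope and intercept exactly", {
  cur <- noiseless_curve(0.0165, 0.153)
  xi_inf <- 0.0165 / 0.1695
  lin <- linearized_fit(cur, xi_inf)
  expect_equal(lin$slope, -0.1695, tolerance = 1e-9)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$intercept, log(xi_inf), tolerance = 1e-9)
  expect_equal(lin$intercept_gap, 0, tolerance = 1e-9)
  expect_equal(lin$n_excluded, 0L)
  # a point sitting exactly at xi_inf is excluded, fit still succeeds
  cur2 <- release_curve(c(cur$times, 1000), c(cur$xi, xi_inf))
  lin2 <- linearized_fit(cur2, xi_inf)
  expect_equal(lin2$n_excluded, 1L)
  expect_equal(lin2$slope, lin$slope, tolerance = 1e-9)
  expect_error(linearized_fit(cur, 1.2), "0, 1")
  # fewer than 3 usable points is a hard failure
  low <- release_curve(0:3, c(0.2, 0.3, 0.35, 0.37))
  expect_error(linearized_fit(low, 0.25), "fewer than 3")
})

test_that("full pipeline recovers generating constants without noise", {
  for (pair in list(ref_pair, ref_pair_ph4)) {
    cur <- noiseless_curve(pair[1], pair[2])
    for (m in c("nonlinear", "linearized")) {
      f <- fit_release(cur, method = m)
      expect_lt(abs(coef(f)[["k1"]] - pair[1]) / pair[1], 1e-6)
      expect_lt(abs(coef(f)[["k_minus1"]] - pair[2]) / pair[2], 1e-6)
    }
  }
  # K from xi_inf equals k1/k-1 identically, by construction
  f <- fit_release(noiseless_curve(0.02, 0.1))
  expect_equal(coef(f)[["K"]],
               coef(f)[["k1"]] / coef(f)[["k_minus1"]],
               tolerance = 1e-14)
  expect_error(release_curve(0:2, c(0, 0.1, 0.2)), "at least 4")
})

test_that("noiseless recovery is exact across random rate constants", {
  pairs <- random_pairs(100, seed = 19)
  for (i in seq_len(nrow(pairs))) {
    f <- fit_release(noiseless_curve(pairs[i, 1], pairs[i, 2]))
    expect_lt(abs(coef(f)[["k1"]] - pairs[i, 1]) / pairs[i, 1], 1e-6)
    expect_lt(abs(coef(f)[["k_minus1"]] - pairs[i, 2]) / pairs[i, 2],
              1e-6)
  }
})

test_that("estimation error shrinks with the noise level", {
  # common random numbers across noise levels: errors scale with sigma
  sigmas <- c(0.01, 0.005, 0.002, 0)
  seeds <- 101:120
  med <- vapply(sigmas, function(s) {
    errs <- vapply(seeds, function(sd) {
      cur <- simulate_release(synthetic_spec(
        rate_constants(0.0165, 0.153), noise_sd = s, seed = sd))
      f <- fit_release(cur)
      abs(coef(f)[["k1"]] - 0.0165) / 0.0165
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-12))
  expect_lt(med[4], 1e-6)
})

test_that("exclusion rule is inert on noiseless data", {
  cur <- noiseless_curve(0.0165, 0.153)
  f <- fit_release(cur, method = "linearized")
  expect_equal(f$linear$n_excluded, 0L)
})

test_that("binding efficiency is the equilibrium bound fraction", {
  expect_equal(binding_efficiency(0), 1)
  expect_equal(binding_efficiency(1), 0.5)
  # published 310 K / pH 7 pair: 90.3% bound at equilibrium
  expect_equal(binding_efficiency(0.0165 / 0.153), 0.9026549,
               tolerance = 1e-6)
  expect_error(binding_efficiency(-1), ">= 0")
})

test_that("release_fit methods behave like a standard model object", {
  cur <- simulate_release(synthetic_spec(rate_constants(0.0165, 0.153),
                                         noise_sd = 0.002, seed = 5))
  f <- fit_release(cur)
  expect_s3_class(f, "release_fit")
  expect_named(coef(f), c("k1", "k_minus1", "k_total", "K", "xi_inf"))
  expect_length(fitted(f), length(cur$times))
  expect_equal(residuals(f), cur$xi - fitted(f))
  expect_equal(predict(f, 0), 0)
  expect_output(print(summary(f)), "Bound fraction")
  sims <- simulate(f, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(length(cur$times), 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 2))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(f))
  # data-frame interface
  f2 <- fit_release(as.data.frame(cur))
  expect_equal(coef(f2), coef(f))
})
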