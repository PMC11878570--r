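test_that("one-component model matches hand-evaluated values and limits", {
  # amplitude limit: G -> 1/N as tau -> 0
  expect_equal(acf_one_component(1e-12, 1, 1e-3, s = 0.17), 1,
               tolerance = 1e-6)
  # hand arithmetic at tau = tau_diff: (1/5) / (2 * sqrt(1 + 0.17^2))
  expect_equal(acf_one_component(1e-3, 5, 1e-3, s = 0.17),
               (1 / 5) / (2 * sqrt(1 + 0.17^2)), tolerance = 1e-12)
  expect_equal(acf_one_component(1e-3, 5, 1e-3, s = 0.17), 0.09859,
               tolerance = 1e-4)
  # decay to zero far beyond the diffusion time
  expect_lt(acf_one_component(1e6 * 1e-3, 3, 1e-3), 1e-4)
})

test_that("model functions reject invalid inputs", {
  expect_error(acf_one_component(-1e-3, 5, 1e-3), "tau")
  expect_error(acf_one_component(1e-3, -5, 1e-3), "n_molecules")
  expect_error(acf_one_component(1e-3, 5, 0), "tau_diff")
  expect_error(acf_one_component(1e-3, 5, 1e-3, s = 1.2), "structure factor")
  expect_error(acf_anomalous(1e-3, 5, 1e-3, alpha = 0), "alpha")
  expect_error(acf_anomalous(1e-3, 5, 1e-3, alpha = -0.5), "alpha")
  expect_error(
    acf_two_component(1e-3, 5, 1e-3, 5e-3, alpha = 0.8, f_fast = 1.2),
    "f_fast")
  expect_error(
    acf_two_component(1e-3, 5, 5e-3, 1e-3, alpha = 0.8, f_fast = 0.5),
    "tau_diff1")
})

test_that("anomalous model reduces to free diffusion at alpha = 1", {
  tau <- 10^seq(-6, 0, length.out = 60)
  expect_equal(
    acf_anomalous(tau, 7, 2e-3, alpha = 1, g_inf = 0),
    acf_one_component(tau, 7, 2e-3), tolerance = 1e-14)
  # ... in both exponent placements
  expect_equal(
    acf_anomalous(tau, 7, 2e-3, alpha = 1, exponent = "printed"),
    acf_one_component(tau, 7, 2e-3), tolerance = 1e-14)
})

test_that("anomalous model matches hand evaluation and offset limit", {
  # at tau = tau_diff the anomaly exponent drops out of the standard
  # placement: (tau/tau_diff)^alpha = 1
  expect_equal(acf_anomalous(2e-3, 10, 2e-3, alpha = 0.8),
               0.1 / (2 * sqrt(1 + 0.17^2)), tolerance = 1e-12)
  # printed placement raises the full factors to alpha instead
  expect_equal(
    acf_anomalous(2e-3, 10, 2e-3, alpha = 0.8, exponent = "printed"),
    0.1 / (2^0.8 * sqrt(1 + 0.17^2)^0.8), tolerance = 1e-12)
  # off the pivot the two placements genuinely differ
  expect_gt(abs(acf_anomalous(1e-2, 10, 2e-3, alpha = 0.8) -
                acf_anomalous(1e-2, 10, 2e-3, alpha = 0.8,
                              exponent = "printed")), 1e-4)
  # G -> g_inf at long lags
  expect_equal(acf_anomalous(1e4, 10, 2e-3, alpha = 0.8, g_inf = 0.02),
               0.02, tolerance = 1e-3)
})

test_that("two-component sum form is the F_fast-weighted mixture", {
  tau <- 10^seq(-6, 0, length.out = 80)
  for (ff in c(0.25, 0.5, 0.9)) {
    mix <- ff * acf_one_component(tau, 1, 1e-3) +
      (1 - ff) * acf_anomalous(tau, 1, 5e-3, alpha = 0.8)
    expect_equal(
      acf_two_component(tau, 4, 1e-3, 5e-3, alpha = 0.8, f_fast = ff),
      mix / 4, tolerance = 1e-14)
  }
  # degenerate fractions collapse to the pure components
  expect_equal(
    acf_two_component(tau, 5, 1e-3, 5e-3, alpha = 0.8, f_fast = 1),
    acf_one_component(tau, 5, 1e-3), tolerance = 1e-14)
  expect_equal(
    acf_two_component(tau, 5, 1e-3, 5e-3, alpha = 0.8, f_fast = 0),
    acf_anomalous(tau, 5, 5e-3, alpha = 0.8), tolerance = 1e-14)
})

test_that("two-component hand-arithmetic example holds", {
  # alpha = 1, f = 0.5: mean of the two free kernels scaled by 1/N
  g1 <- 1 / ((1 + 1) * sqrt(1 + 0.17^2 * 1))
  g2 <- 1 / ((1 + 0.5) * sqrt(1 + 0.17^2 * 0.5))
  expect_equal(
    acf_two_component(1e-3, 5, 1e-3, 2e-3, alpha = 1, f_fast = 0.5),
    (1 / 5) * 0.5 * (g1 + g2), tolerance = 1e-12)
})

test_that("literal product form has the amplitude defect it is kept to expose", {
  # G(0) -> F(1-F)/N instead of 1/N
  g0 <- acf_two_component(1e-12, 5, 1e-3, 5e-3, alpha = 0.8,
                          f_fast = 0.6, form = "literal_product")
  expect_equal(g0, 0.6 * 0.4 / 5, tolerance = 1e-5)
})

test_that("G is strictly decreasing in lag for the additive models", {
  tau <- 10^seq(-6, 1, length.out = 120)
  grids <- list(
    acf_one_component(tau, 3, 1e-3),
    acf_anomalous(tau, 3, 2e-3, alpha = 0.7),
    acf_two_component(tau, 3, 1e-3, 8e-3, alpha = 1, f_fast = 0.4))
  for (g in grids) expect_true(all(diff(g) < 0))
})

test_that("zero-lag amplitude approaches 1/N + g_inf for all models", {
  for (N in c(1, 5, 50)) {
    expect_equal(acf_one_component(1e-9, N, 1e-3), 1 / N,
                 tolerance = 1e-3)
    expect_equal(acf_anomalous(1e-9, N, 1e-3, alpha = 0.8, g_inf = 0.01),
                 1 / N + 0.01, tolerance = 1e-3)
    expect_equal(
      acf_two_component(1e-9, N, 1e-3, 5e-3, alpha = 0.8, f_fast = 0.6),
      1 / N, tolerance = 1e-3)
  }
})

test_that("models are smooth in their parameters (no internal branches)", {
  tau <- c(1e-4, 1e-3, 1e-2)
  base <- list(n_molecules = 5, tau_diff1 = 1e-3, tau_diff2 = 5e-3,
               alpha = 0.8, f_fast = 0.6)
  g0 <- do.call(acf_two_component, c(list(tau = tau), base))
  for (nm in names(base)) {
    pert <- base
    pert[[nm]] <- pert[[nm]] * (1 + 1e-8)
    g1 <- do.call(acf_two_component, c(list(tau = tau), pert))
    expect_lt(max(abs(g1 - g0) / abs(g0)), 1e-4)
  }
})
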