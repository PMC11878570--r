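test_that("all generators are reproducible from their seed", {
  a <- simulate_acf(two_comp_truth(), noise_sd = 0.02, n_curves = 2,
                    seed = 1)
  b <- simulate_acf(two_comp_truth(), noise_sd = 0.02, n_curves = 2,
                    seed = 1)
  expect_identical(a[[2]]$g, b[[2]]$g)

  d1 <- simulate_droplets(2000, 0.3, 0.4, seed = 2)
  d2 <- simulate_droplets(2000, 0.3, 0.4, seed = 2)
  expect_identical(d1$hex_amplitude, d2$hex_amplitude)

  t1 <- simulate_dose_response(1e6, 10^seq(4, 8), noise_sd = 3, seed = 3)
  t2 <- simulate_dose_response(1e6, 10^seq(4, 8), noise_sd = 3, seed = 3)
  expect_identical(t1$response_pct, t2$response_pct)

  k1 <- simulate_timecourse(0.2, 0.3, noise_sd = 2, seed = 4)
  k2 <- simulate_timecourse(0.2, 0.3, noise_sd = 2, seed = 4)
  expect_identical(k1$indel_pct, k2$indel_pct)

  s1 <- simulate_fcs_trace(list(concentration = 1e-8, tau_diff = 1e-3,
                                brightness = 3e4),
                           duration = 0.5, bin_time = 1e-4, seed = 5)
  s2 <- simulate_fcs_trace(list(concentration = 1e-8, tau_diff = 1e-3,
                                brightness = 3e4),
                           duration = 0.5, bin_time = 1e-4, seed = 5)
  expect_identical(s1$counts, s2$counts)
})

test_that("seeded generators restore the caller's RNG state", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_acf(two_comp_truth(), noise_sd = 0.02, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noiseless analytic curves equal the model exactly", {
  cv <- simulate_acf(two_comp_truth(5), noise_sd = 0)[[1]]
  expected <- acf_two_component(cv$lags, 5, 1e-3, 5e-3, alpha = 0.8,
                                f_fast = 0.6)
  expect_identical(cv$g, expected)
  expect_null(cv$g_se)
})

test_that("noisy analytic curves carry their true noise SD as g_se", {
  curves <- simulate_acf(two_comp_truth(5), noise_sd = 0.02,
                         n_curves = 200, seed = 8)
  g_true <- acf_two_component(curves[[1]]$lags, 5, 1e-3, 5e-3,
                              alpha = 0.8, f_fast = 0.6)
  resid <- vapply(curves, function(cv) (cv$g - g_true) / cv$g_se,
                  numeric(length(g_true)))
  # standardized residuals should be ~N(0,1) per lag
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(abs(sd(resid) - 1), 0.05)
  # noise grows with lag (correlator-like variance profile)
  se_rel <- curves[[1]]$g_se / pmax(abs(g_true), max(g_true) * 1e-3)
  expect_gt(se_rel[length(se_rel)], se_rel[1] * 2)
})

test_that("zero-brightness species yields a pure background trace", {
  tr <- simulate_fcs_trace(list(concentration = 1e-8, tau_diff = 1e-3,
                                brightness = 0),
                           duration = 1, bin_time = 1e-3,
                           background = 2000, seed = 9)
  expect_equal(mean(tr$counts), 2, tolerance = 0.2)
  cv <- acf_direct(tr, max_lag = 0.05)
  expect_lt(max(abs(cv$g)), 0.2)  # uncorrelated shot noise
})

test_that("the particle guard rejects absurd concentrations", {
  expect_error(
    simulate_fcs_trace(list(concentration = 1e-3, tau_diff = 1e-3,
                            brightness = 1e4),
                       duration = 1, bin_time = 1e-3, seed = 1),
    "particles")
})

test_that("simulator rejects more than two species", {
  sp <- list(concentration = 1e-9, tau_diff = 1e-3, brightness = 1e4)
  expect_error(
    simulate_fcs_trace(list(sp, sp, sp), duration = 1,
                       bin_time = 1e-3),
    "2 species")
})

test_that("droplet generator hits its degenerate endpoints", {
  thr <- list(hex = 4000, fam = 4000)
  w0 <- simulate_droplets(5000, 0.3, 0, seed = 10)
  expect_lt(quantify_droplets(w0, thr, min_droplets = 1000)$pct_dsb, 3)
  w1 <- simulate_droplets(5000, 0.3, 1, seed = 11)
  expect_gt(quantify_droplets(w1, thr, min_droplets = 1000)$pct_dsb, 97)
})

test_that("time-course generator obeys its closed-form limits", {
  tc <- simulate_timecourse(k_cut = 0.15, k_repair = 1e6, plateau = 80,
                            times = seq(0, 54, 0.5))
  # fast repair: indel course is plateau * (1 - exp(-k_cut t))
  expect_equal(tc$indel_pct, 80 * (1 - exp(-0.15 * tc$time_h)),
               tolerance = 1e-4)
  # DSBs stay non-negative and resolve at long times
  tc2 <- simulate_timecourse(k_cut = 0.3, k_repair = 0.2,
                             times = seq(0, 100, 1))
  expect_true(all(tc2$dsb_pct >= 0))
  expect_lt(tc2$dsb_pct[length(tc2$dsb_pct)], 0.1)
  # equal rates use the k t exp(-kt) limit continuously
  tc3 <- simulate_timecourse(0.2, 0.2, times = c(1, 5))
  tc4 <- simulate_timecourse(0.2, 0.2 + 1e-9, times = c(1, 5))
  expect_equal(tc3$dsb_pct, tc4$dsb_pct, tolerance = 1e-5)
})

test_that("dose generator clamps to the percent scale", {
  d <- simulate_dose_response(1e6, 10^seq(4, 8, 0.5), top = 99,
                              noise_sd = 10, seed = 12,
                              n_replicates = 3)
  expect_true(all(d$response_pct >= 0 & d$response_pct <= 100))
  expect_equal(nrow(d), 9 * 3)
})
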