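test_that("exact 4PL data are recovered exactly, with the midpoint property", {
  doses <- 10^seq(4, 8, length.out = 9)
  d <- simulate_dose_response(ec50 = 1e6, doses = doses, bottom = 0,
                              top = 80, hill = 1, noise_sd = 0)
  fit <- dose_response(response_pct ~ dose_per_cell, data = d)
  cf <- coef(fit)
  expect_equal(cf[["ec50"]], 1e6, tolerance = 1e-4)
  expect_equal(cf[["top"]], 80, tolerance = 1e-4)
  expect_equal(cf[["bottom"]], 0, tolerance = 1e-3)
  expect_equal(cf[["hill"]], 1, tolerance = 1e-4)
  # response at the EC50 is the middle of the span
  expect_equal(predict(fit, cf[["ec50"]]), 40, tolerance = 1e-3)
  expect_gt(fit$r2, 0.999999)
})

test_that("noisy 4PL data recover the EC50 within 25%", {
  doses <- 10^seq(4, 8, length.out = 9)
  d <- simulate_dose_response(ec50 = 1e6, doses = doses, top = 80,
                              noise_sd = 3, seed = 13, n_replicates = 2)
  fit <- dose_response(d$dose_per_cell, d$response_pct)
  expect_lt(abs(coef(fit)[["ec50"]] - 1e6) / 1e6, 0.25)
})

test_that("degenerate dose tables are rejected as non-identifiable", {
  doses <- 10^seq(4, 8, length.out = 9)
  expect_error(dose_response(doses, rep(50, 9)), "identifiable")
  expect_error(dose_response(doses[1:4], c(1, 2, 3, 4)), "5 dose")
})

test_that("ec_at inverts the fitted curve", {
  doses <- 10^seq(4, 8, length.out = 9)
  d <- simulate_dose_response(ec50 = 1e6, doses = doses, top = 80,
                              hill = 1, noise_sd = 0)
  fit <- dose_response(d$dose_per_cell, d$response_pct)
  expect_equal(ec_at(fit, 50), coef(fit)[["ec50"]], tolerance = 1e-9)
  # hill = 1: EC90 = 9 x EC50
  expect_equal(ec_at(fit, 90), 9 * coef(fit)[["ec50"]],
               tolerance = 1e-3)
  # round trip: response at the EC90 is 90% of the span
  cf <- coef(fit)
  resp <- predict(fit, ec_at(fit, 90))
  expect_equal((resp - cf[["bottom"]]) / (cf[["top"]] - cf[["bottom"]]),
               0.9, tolerance = 1e-6)
  expect_error(ec_at(fit, 0), "level")
  expect_error(ec_at(fit, 100), "level")
})

test_that("fold change is a ratio with the inverse property", {
  expect_equal(round(fold_change(2.4e6, 5.7e4)), 42)
  expect_equal(fold_change(1e6, 1e6), 1)
  expect_equal(fold_change(3e6, 1e5) * fold_change(1e5, 3e6), 1,
               tolerance = 1e-12)
  expect_error(fold_change(1e6, 0), "> 0")
})

test_that("dose-to-concentration regression predicts and flags extrapolation", {
  doses <- c(0.24, 0.75, 1.9, 3.8, 7.5, 15) * 1e7
  conc <- 2.6e-7 * doses  # exactly linear, ~39 nM at the top dose
  reg <- dose_conc_regression(doses, conc)
  expect_equal(reg$r2, 1, tolerance = 1e-10)
  expect_equal(predict(reg, 1e7), 2.6, tolerance = 1e-6)
  # dose 0 returns the intercept (and is itself flagged as
  # extrapolation below the fitted range)
  expect_warning(p0 <- predict(reg, 0), "extrapolat")
  expect_equal(p0, reg$intercept, tolerance = 1e-10)
  expect_warning(predict(reg, 100e7), "extrapolat")
  expect_error(dose_conc_regression(doses[1:2], conc[1:2]), "3 points")
})

test_that("half-max time matches the closed form of the kinetics generator", {
  # fast repair: indels are a saturating exponential with rate k_cut,
  # so half-max falls at log(2)/k_cut = 4.62 h
  tc <- simulate_timecourse(k_cut = 0.15, k_repair = 1e6, plateau = 80,
                            times = seq(0, 54, 1))
  t_half <- halfmax_time(time_course(tc$time_h, tc$indel_pct))
  expect_equal(t_half, log(2) / 0.15, tolerance = 0.05)
})

test_that("half-max falls back to interpolation for a step course", {
  tc <- time_course(c(0, 4, 8, 12), c(0, 0, 80, 80))
  t_half <- halfmax_time(tc)
  expect_gte(t_half, 4); expect_lte(t_half, 8)
  expect_error(halfmax_time(time_course(c(0, 4), c(0, 0))), "zero")
})

test_that("editing rate is the windowed finite-difference slope", {
  # linear 0 -> 53% over 5 h: 10.6 %/h in any sub-window
  tc <- time_course(c(0, 5), c(0, 53))
  expect_equal(editing_rate(tc, c(0, 1)), 10.6, tolerance = 1e-9)
  flat <- time_course(c(0, 2, 4), c(30, 30, 30))
  expect_equal(editing_rate(flat, c(0, 4)), 0)
  expect_error(editing_rate(tc, c(0, 0)), "positive width")
  expect_error(editing_rate(tc, c(0, 10)), "within")
})

test_that("time_course validates its invariants", {
  expect_error(time_course(c(2, 1), c(0, 10)), "non-decreasing")
  expect_error(time_course(c(0, 1), c(0, 120)), "percent")
})

test_that("dose_response_fit methods are coherent", {
  doses <- 10^seq(4, 8, length.out = 9)
  d <- simulate_dose_response(ec50 = 1e6, doses = doses, top = 80,
                              noise_sd = 2, seed = 17)
  fit <- dose_response(d$dose_per_cell, d$response_pct)
  expect_equal(residuals(fit), d$response_pct - fitted(fit),
               tolerance = 1e-12)
  expect_output(print(fit), "EC50")
  expect_output(summary(fit), "EC90")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_true(all(c("dose_per_cell", "response_pct") %in%
                    names(sims[[1]])))
})
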