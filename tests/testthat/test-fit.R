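test_that("noiseless curves are recovered exactly by all three models", {
  cv1 <- simulate_acf(one_comp_truth(5, 2e-3), noise_sd = 0)[[1]]
  f1 <- fcs_fit(cv1, model = "one_component")
  expect_true(f1$converged)
  expect_equal(coef(f1)[["n_molecules"]], 5, tolerance = 1e-6)
  expect_equal(coef(f1)[["tau_diff"]], 2e-3, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-12)

  cva <- simulate_acf(list(model = "anomalous", n_molecules = 8,
                           tau_diff = 3e-3, alpha = 0.7, g_inf = 0),
                      noise_sd = 0)[[1]]
  fa <- fcs_fit(cva, model = "anomalous")
  expect_equal(coef(fa)[["alpha"]], 0.7, tolerance = 1e-4)
  expect_equal(coef(fa)[["n_molecules"]], 8, tolerance = 1e-4)

  cv2 <- simulate_acf(two_comp_truth(5), noise_sd = 0)[[1]]
  f2 <- fcs_fit(cv2, model = "two_component")
  expect_equal(coef(f2)[["n_molecules"]], 5, tolerance = 1e-6)
  expect_equal(coef(f2)[["tau_diff1"]], 1e-3, tolerance = 1e-4)
  expect_equal(coef(f2)[["tau_diff2"]], 5e-3, tolerance = 1e-4)
  expect_equal(coef(f2)[["f_fast"]], 0.6, tolerance = 1e-4)
})

test_that("fit enforces the lag-grid preconditions", {
  cv <- acf_curve(10^seq(-5, -4.5, length.out = 25), rep(0.2, 25))
  expect_error(fcs_fit(cv), "3 decades")
  cv2 <- acf_curve(10^seq(-5, 0, length.out = 10), rep(0.2, 10))
  expect_error(fcs_fit(cv2), "20 lag")
})

test_that("noisy two-component curves are recovered within tolerance", {
  curves <- simulate_acf(two_comp_truth(5), noise_sd = 0.02,
                         n_curves = 12, seed = 21)
  fits <- lapply(curves, fcs_fit)
  nh <- vapply(fits, function(f) coef(f)[["n_molecules"]], numeric(1))
  ff <- vapply(fits, function(f) coef(f)[["f_fast"]], numeric(1))
  expect_lt(median(abs(nh - 5) / 5), 0.1)
  expect_lt(abs(median(ff) - 0.6), 0.05)
  # weighted fits of correctly specified noise have reduced chi2 near 1
  chi <- vapply(fits, function(f) f$chi2, numeric(1))
  expect_gt(median(chi), 0.5); expect_lt(median(chi), 2)
})

test_that("pure white noise fails QC rather than masquerading as a fit", {
  set.seed(5)
  lags <- 10^seq(-5, 0, length.out = 60)
  cv <- acf_curve(lags, rnorm(60, 0, 0.05),
                  g_se = rep(0.001, 60))  # misspecified errors -> huge chi2
  f <- fcs_fit(cv, model = "two_component")
  f <- qc_filter(f)
  expect_equal(f$qc_status, "fail")
  expect_true(any(c("high_chi2", "no_convergence") %in% f$qc_reasons))
})

test_that("select_model picks the lower chi-square with a parsimony tie-break", {
  cv2 <- simulate_acf(two_comp_truth(5), noise_sd = 0.02, seed = 31)[[1]]
  f1 <- fcs_fit(cv2, model = "one_component")
  f2 <- fcs_fit(cv2, model = "two_component")
  expect_equal(select_model(f1, f2)$model, "two_component")

  # on genuinely one-component data the two models tie (the 2C fit
  # degenerates); ties go to the simpler model
  cv1 <- simulate_acf(one_comp_truth(5, 2e-3), noise_sd = 0)[[1]]
  g1 <- fcs_fit(cv1, model = "one_component")
  tie <- g1; tie$model <- "two_component"   # synthetic exact tie
  expect_equal(select_model(g1, tie)$model, "one_component")

  bad <- f2; bad$converged <- FALSE
  expect_equal(select_model(f1, bad)$model, "one_component")
  bad1 <- f1; bad1$converged <- FALSE
  expect_error(select_model(bad1, bad), "neither")
})

test_that("each QC threshold triggers its named rejection reason", {
  cv <- simulate_acf(two_comp_truth(5), noise_sd = 0.02, seed = 41)[[1]]
  f <- fcs_fit(cv, model = "two_component")
  stopifnot(f$converged)
  # rebuild fits with doctored parameters; qc_filter is a pure function
  # of the recorded values
  doctor <- function(fit, ...) {
    ch <- list(...)
    for (nm in names(ch)) {
      if (nm == "chi2") fit$chi2 <- ch[[nm]]
      else fit$coefficients[[nm]] <- ch[[nm]]
    }
    fit
  }
  expect_equal(qc_filter(doctor(f, tau_diff1 = 4e-4))$qc_reasons,
               "free_rna")
  expect_equal(qc_filter(doctor(f, tau_diff1 = 1.2e-2))$qc_reasons,
               "aggregation")
  expect_equal(qc_filter(doctor(f, alpha = 0.2))$qc_reasons, "low_alpha")
  expect_equal(qc_filter(doctor(f, chi2 = 31))$qc_reasons, "high_chi2")
  # reasons are exhaustive, not first-hit
  multi <- qc_filter(doctor(f, tau_diff1 = 4e-4, alpha = 0.1, chi2 = 40))
  expect_setequal(multi$qc_reasons,
                  c("free_rna", "low_alpha", "high_chi2"))
  # a compliant fit passes with no reasons
  ok <- qc_filter(doctor(f, tau_diff1 = 2e-3, alpha = 0.8, chi2 = 5))
  expect_equal(ok$qc_status, "pass")
  expect_length(ok$qc_reasons, 0)
  # one-component fit when two components were requested
  f1 <- fcs_fit(cv, model = "one_component")
  expect_true("no_second_component" %in% qc_filter(f1)$qc_reasons)
  # thresholds are configurable
  loose <- qc_filter(doctor(f, tau_diff1 = 4e-4),
                     thresholds = qc_thresholds(tau1_min = 1e-4))
  expect_equal(loose$qc_status, "pass")
  # determinism: same fit, same thresholds, same outcome
  expect_identical(qc_filter(f)$qc_reasons, qc_filter(f)$qc_reasons)
})

test_that("condition summary counts passes and flags sparse conditions", {
  cv <- simulate_acf(two_comp_truth(5), noise_sd = 0.02, seed = 51)[[1]]
  f <- qc_filter(fcs_fit(cv))
  stopifnot(f$qc_status == "pass")
  fail <- f; fail$qc_status <- "fail"; fail$qc_reasons <- "high_chi2"
  fits <- c(rep(list(f), 25), rep(list(fail), 5))
  s <- condition_summary(fits, min_pass = 20)
  expect_equal(s$n_total, 30); expect_equal(s$n_pass, 25)
  expect_true(s$accepted); expect_equal(s$flag, "ok")

  s2 <- condition_summary(c(rep(list(f), 15), rep(list(fail), 15)),
                          min_pass = 20)
  expect_false(s2$accepted); expect_equal(s2$flag, "insufficient_n")

  s0 <- condition_summary(list())
  expect_equal(s0$n_pass, 0); expect_equal(s0$flag, "insufficient_n")
})

test_that("fcs_fit methods are coherent", {
  cv <- simulate_acf(two_comp_truth(5), noise_sd = 0.02, seed = 61)[[1]]
  f <- fcs_fit(cv)
  expect_equal(predict(f), fitted(f), tolerance = 1e-12)
  expect_equal(residuals(f), cv$g - fitted(f), tolerance = 1e-12)
  expect_output(print(f), "two_component")
  expect_output(summary(f), "residuals")
  sims <- simulate(f, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "acf_curve")
})
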