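#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Least-squares fit of
#' response = bottom + (top - bottom) / (1 + (ec50 / x)^hill)
#' on percentage responses, the standard sigmoidal model for editing
#' efficiency versus delivered dose. Internally the fit runs on
#' log10(dose) for conditioning, with bottom constrained >= 0 and
#' top <= 100 (responses are percentages) and hill > 0.
#'
#' Accepts either a formula plus data frame
#' (`dose_response(response_pct ~ dose_per_cell, data)`) or two
#' numeric vectors.
#'
#' @param x A formula (response ~ dose) or a numeric vector of doses
#'   (e.g. molecules per cell), all > 0 except that a zero dose is
#'   taken as the bottom anchor.
#' @param response Percent responses, same length as the doses
#'   (ignored when `x` is a formula).
#' @param data Data frame supplying the formula variables.
#' @param ... Unused.
#' @return An object of class `"dose_response_fit"` with
#'   `coefficients` (`bottom`, `top`, `ec50`, `hill`), `r2`,
#'   `n_points`, `doses`, `response`, `fitted`.
#' @examples
#' d <- simulate_dose_response(ec50 = 1e6, doses = 10^seq(4, 8, 0.5),
#'                             top = 80, noise_sd = 0, seed = 1)
#' fit <- dose_response(response_pct ~ dose_per_cell, d)
#' coef(fit)["ec50"]
#' @export
dose_response <- function(x, response = NULL, data = NULL, ...) {
  if (inherits(x, "formula")) {
    mf <- model.frame(x, data)
    response <- mf[[1]]
    doses <- mf[[2]]
  } else {
    doses <- as.numeric(x)
    response <- as.numeric(response)
  }
  keep <- is.finite(doses) & is.finite(response)
  doses <- doses[keep]; response <- response[keep]
  if (length(unique(doses)) < 5) {
    stop("need at least 5 dose levels", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (sd(response) < 1e-8 || diff(range(response)) < 1) {
    stop("responses show no transition: EC50 is not identifiable",
         call. = FALSE)
  }

  # 4PL on the log10 dose axis; zero dose maps to the bottom asymptote
  eval_4pl <- function(bottom, top, log_ec50, hill, dose) {
    ld <- suppressWarnings(log10(dose))      # -Inf at dose 0
    frac <- 1 / (1 + 10^(hill * (log_ec50 - ld)))
    frac[dose == 0] <- 0
    bottom + (top - bottom) * frac
  }
  # transforms: bottom in [0,100], top in (bottom, 100], hill > 0
  unpack <- function(p) {
    bottom <- 100 * plogis(p[1])
    top <- bottom + (100 - bottom) * plogis(p[2])
    list(bottom = bottom, top = top, log_ec50 = p[3], hill = exp(p[4]))
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    response - eval_4pl(q$bottom, q$top, q$log_ec50, q$hill, doses)
  }
  # data-driven start: bottom/top from response extremes, EC50 from the
  # dose nearest the half response
  r_lo <- max(min(response), 0); r_hi <- min(max(response), 100)
  half <- (r_lo + r_hi) / 2
  pos <- doses > 0
  ec0 <- doses[pos][which.min(abs(response[pos] - half))]
  start <- c(qlogis(min(max(r_lo / 100, 0.005), 0.95)),
             qlogis(min(max((r_hi - r_lo) / (100 - min(r_lo, 99)), 0.01),
                        0.99)),
             log10(ec0), 0)
  starts <- list(start, start + c(0, 0, 1, 0), start + c(0, 0, -1, 0))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$par))) next
    ssr <- sum(res$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = res, ssr = ssr)
  }
  if (is.null(best)) stop("4PL fit failed to converge", call. = FALSE)
  q <- unpack(best$fit$par)
  ec50 <- 10^q$log_ec50
  if (ec50 < min(doses[pos]) / 1e3 || ec50 > max(doses) * 1e3) {
    stop("fitted EC50 far outside the dosed range: transition not ",
         "identifiable", call. = FALSE)
  }
  fitted_vals <- eval_4pl(q$bottom, q$top, q$log_ec50, q$hill, doses)
  r2 <- 1 - best$ssr / sum((response - mean(response))^2)
  structure(
    list(coefficients = c(bottom = q$bottom, top = q$top, ec50 = ec50,
                          hill = q$hill),
         r2 = r2, n_points = length(doses),
         doses = doses, response = response, fitted = fitted_vals),
    class = "dose_response_fit")
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
fitted.dose_response_fit <- function(object, ...) object$fitted

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$response - object$fitted
}

#' Predict percent response at given doses
#'
#' @param object A `"dose_response_fit"`.
#' @param doses Doses to evaluate at; defaults to the fitted doses.
#' @param ... Unused.
#' @export
predict.dose_response_fit <- function(object, doses = object$doses, ...) {
  cf <- object$coefficients
  ld <- suppressWarnings(log10(doses))
  frac <- 1 / (1 + 10^(cf[["hill"]] * (log10(cf[["ec50"]]) - ld)))
  frac[doses == 0] <- 0
  unname(cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) * frac)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50 = %.3g, hill = %.3g\n", cf[["ec50"]], cf[["hill"]]))
  cat(sprintf("  bottom = %.3g%%, top = %.3g%%, R2 = %.3f (n = %d)\n",
              cf[["bottom"]], cf[["top"]], x$r2, x$n_points))
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  EC90 = %.3g (dose for 90%% of maximal response)\n",
              ec_at(object, 90)))
  invisible(object)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  pos <- x$doses > 0
  plot(x$doses[pos], x$response[pos], log = "x",
       xlab = "dose (molecules/cell)", ylab = "response (%)", ...)
  grid_d <- 10^seq(log10(min(x$doses[pos])), log10(max(x$doses)),
                   length.out = 200)
  lines(grid_d, predict(x, grid_d), col = 2, lwd = 2)
  abline(v = x$coefficients[["ec50"]], lty = 3)
  invisible(x)
}

#' Simulate replicate dose tables from a fitted curve
#'
#' @param object A `"dose_response_fit"`.
#' @param nsim Number of replicate tables.
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise SD in percentage points; default 3.
#' @param ... Unused.
#' @export
simulate.dose_response_fit <- function(object, nsim = 1, seed = NULL,
                                       noise_sd = 3, ...) {
  cf <- object$coefficients
  lapply(seq_len(nsim), function(i) {
    simulate_dose_response(
      ec50 = cf[["ec50"]], doses = object$doses,
      bottom = cf[["bottom"]], top = cf[["top"]], hill = cf[["hill"]],
      noise_sd = noise_sd,
      seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
}

#' Dose at a given percent of the maximal response
#'
#' Inverts the fitted 4PL at bottom + level/100 * (top - bottom).
#' Closed form: dose = ec50 * (level / (100 - level))^(1/hill), so
#' `level = 50` returns the EC50 exactly and, for hill = 1,
#' `level = 90` returns 9 x EC50.
#'
#' @param fit A `"dose_response_fit"`.
#' @param level Percent of the response span, in (0, 100).
#' @return Dose in the fitted dose units.
#' @export
ec_at <- function(fit, level) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!is.finite(level) || level <= 0 || level >= 100) {
    stop("level must lie in (0, 100)", call. = FALSE)
  }
  cf <- fit$coefficients
  cf[["ec50"]] * (level / (100 - level))^(1 / cf[["hill"]])
}

#' Fold-change between two EC50s
#'
#' The factor by which the reference modality's dose requirement
#' exceeds the test modality's: ec50_reference / ec50_test.
#'
#' @param ec50_reference,ec50_test Positive doses.
#' @return Dimensionless ratio.
#' @examples
#' fold_change(2.4e6, 5.7e4)  # ~42-fold dose reduction
#' @export
fold_change <- function(ec50_reference, ec50_test) {
  if (any(!is.finite(ec50_reference)) || any(ec50_reference <= 0) ||
      any(!is.finite(ec50_test)) || any(ec50_test <= 0)) {
    stop("EC50s must be > 0", call. = FALSE)
  }
  ec50_reference / ec50_test
}

#' Linear regression of nuclear concentration on delivered dose
#'
#' Fits concentration_nM = slope * dose + intercept by ordinary least
#' squares, the calibration that converts an arbitrary dose into the
#' nuclear concentration it produces.
#'
#' @param dose_per_cell Delivered doses, molecules per cell (>= 3
#'   points).
#' @param concentration_nM Measured nuclear concentrations, nM.
#' @return An object of class `"dose_conc_regression"` with `slope`
#'   (nM per molecule/cell), `intercept` (nM), `r2`, `n_points`,
#'   `dose_range`, and the underlying `lm` fit.
#' @export
dose_conc_regression <- function(dose_per_cell, concentration_nM) {
  keep <- is.finite(dose_per_cell) & is.finite(concentration_nM)
  dose_per_cell <- dose_per_cell[keep]
  concentration_nM <- concentration_nM[keep]
  if (length(dose_per_cell) < 3) {
    stop("regression requires at least 3 points", call. = FALSE)
  }
  fit <- lm(concentration_nM ~ dose_per_cell)
  sst <- sum((concentration_nM - mean(concentration_nM))^2)
  r2 <- 1 - sum(residuals(fit)^2) / sst
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n_points = length(dose_per_cell),
         dose_range = range(dose_per_cell), lm = fit),
    class = "dose_conc_regression")
}

#' @export
print.dose_conc_regression <- function(x, ...) {
  cat("Dose -> nuclear concentration regression\n")
  cat(sprintf("  conc (nM) = %.3g * dose + %.3g;  R2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_points))
  invisible(x)
}

#' Predict nuclear concentration from a delivered dose
#'
#' @param object A `"dose_conc_regression"`.
#' @param dose Doses in molecules per cell. A warning is issued when a
#'   dose lies beyond twice the fitted range (extrapolation).
#' @param ... Unused.
#' @return Concentration in nM.
#' @export
predict.dose_conc_regression <- function(object, dose, ...) {
  lo <- object$dose_range[1] / 2
  hi <- object$dose_range[2] * 2
  if (any(dose < lo | dose > hi)) {
    warning("dose outside 2x the fitted range; extrapolating",
            call. = FALSE)
  }
  object$slope * dose + object$intercept
}

#' Time-course container for editing kinetics
#'
#' @param time_h Times in hours, non-decreasing.
#' @param value_pct Percent values (DSB or indels), in [0, 100].
#' @param condition Label.
#' @param dose_per_cell Delivered dose, molecules/cell.
#' @return A data frame of class `"time_course"`.
#' @export
time_course <- function(time_h, value_pct, condition = "all",
                        dose_per_cell = NA_real_) {
  time_h <- as.numeric(time_h); value_pct <- as.numeric(value_pct)
  stopifnot(length(time_h) == length(value_pct))
  if (any(diff(time_h) < 0)) {
    stop("times must be non-decreasing", call. = FALSE)
  }
  if (any(value_pct < 0 | value_pct > 100)) {
    stop("values must lie in [0, 100] percent", call. = FALSE)
  }
  structure(
    data.frame(time_h = time_h, value_pct = value_pct,
               condition = condition, dose_per_cell = dose_per_cell,
               stringsAsFactors = FALSE),
    class = c("time_course", "data.frame"))
}

#' Time of half-maximal editing
#'
#' Half-max is defined relative to the fitted plateau, not to 100%.
#' The plateau is the mean of the final fifth of the course when that
#' region has demonstrably flattened (spread < 5% of the maximum);
#' otherwise it is the `top` of a 4PL fitted in time, falling back to
#' the maximum observed value when the sigmoid is not identifiable.
#' The crossing time of half the plateau is then read from the
#' measured course by linear interpolation, which keeps the estimate
#' accurate when the kinetics are saturating-exponential rather than
#' exactly logistic.
#'
#' @param tc A [time_course()] or data frame with `time_h` and
#'   `value_pct`.
#' @return Time in hours.
#' @examples
#' tc <- simulate_timecourse(k_cut = 0.15, k_repair = 1e6, plateau = 80,
#'                           times = seq(0, 54, 2))
#' halfmax_time(time_course(tc$time_h, tc$indel_pct))  # ~ log(2)/0.15
#' @export
halfmax_time <- function(tc) {
  t <- tc$time_h; v <- tc$value_pct
  if (max(v) <= 0) stop("course never rises above zero", call. = FALSE)
  tail_win <- t >= min(t) + 0.8 * diff(range(t))
  flat <- sum(tail_win) >= 2 &&
    diff(range(v[tail_win])) < 0.05 * max(v)
  plateau <- if (flat) {
    mean(v[tail_win])
  } else {
    fit <- tryCatch(dose_response(t, v), error = function(e) NULL)
    if (!is.null(fit)) coef(fit)[["top"]] else max(v)
  }
  half <- plateau / 2
  above <- which(v >= half)
  if (!length(above)) {  # fitted plateau above anything observed
    half <- max(v) / 2
    above <- which(v >= half)
  }
  if (!length(above)) stop("course never crosses half-max", call. = FALSE)
  i <- above[1]
  if (i == 1) return(t[1])
  # linear interpolation between the bracketing samples
  unname(t[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) *
           (t[i] - t[i - 1]))
}

#' Editing rate over a time window
#'
#' Finite-difference slope of the percent-edited course over
#' `[h_start, h_end]`, with linear interpolation of the values at the
#' window endpoints.
#'
#' @param tc A [time_course()] or data frame with `time_h`,
#'   `value_pct`.
#' @param window Numeric length-2: start and end times in hours; both
#'   must lie within the measured range and the window must have
#'   positive width.
#' @return Rate in percentage points per hour.
#' @examples
#' tc <- time_course(c(0, 5), c(0, 53))
#' editing_rate(tc, c(0, 1))  # 10.6 %/h
#' @export
editing_rate <- function(tc, window) {
  stopifnot(length(window) == 2)
  t <- tc$time_h; v <- tc$value_pct
  if (window[2] <= window[1]) {
    stop("window must have positive width", call. = FALSE)
  }
  if (window[1] < min(t) || window[2] > max(t)) {
    stop("window endpoints must lie within the measured times",
         call. = FALSE)
  }
  v_start <- approx(t, v, xout = window[1])$y
  v_end <- approx(t, v, xout = window[2])$y
  (v_end - v_start) / (window[2] - window[1])
}
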