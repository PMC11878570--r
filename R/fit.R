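#' Fit a diffusion model to an autocorrelation curve
#'
#' Weighted least-squares fit of the one-component ([acf_one_component()]),
#' anomalous ([acf_anomalous()]), or two-component
#' ([acf_two_component()]) model to an [acf_curve()], with the
#' structure factor held fixed. This is the workhorse that turns raw
#' correlation curves into molecule counts and diffusion times.
#'
#' Weights are 1/g_se^2 when the curve carries per-lag standard
#' errors, otherwise unweighted. Fitting uses Levenberg-Marquardt on
#' log-transformed scale parameters; the two-component model
#' parameterizes the slow time as tau_diff2 = tau_diff1 * (1 + delta),
#' delta > 0, so the fast/slow labels cannot switch. Initialization is
#' data-driven (amplitude from the first lag, the fast time from where
#' the curve falls to half its first-decade plateau) and three
#' additional deterministically jittered starts guard against local
#' minima; the best converged start by chi-square wins.
#'
#' Parameter bounds: N in (1e-3, 1e4); diffusion times in (1e-6, 1) s;
#' alpha in (0.05, 1.5); f_fast in [0, 1].
#'
#' @param curve An [acf_curve()] with at least 20 lags spanning at
#'   least 3 decades.
#' @param model `"two_component"` (default), `"one_component"`, or
#'   `"anomalous"`.
#' @param s Structure factor, fixed during the fit; default 0.17.
#' @param chi2 Chi-square normalization: `"reduced"` (default;
#'   weighted sum of squares divided by n_lags - n_params) or `"raw"`.
#' @param exponent Anomaly-exponent placement; see [acf_anomalous()].
#' @param form Two-component form; see [acf_two_component()].
#' @param n_starts Number of jittered restarts in addition to the
#'   data-driven start; default 3.
#' @return An object of class `"fcs_fit"`: fields `model`,
#'   `coefficients` (named vector including the fixed `s`), `chi2`,
#'   `chi2_mode`, `converged`, `qc_status` (`"pending"` until
#'   [qc_filter()] is applied), `qc_reasons`, `curve`, `fitted`,
#'   `weights`, `n_obs`, `n_par`.
#' @examples
#' curve <- simulate_acf(
#'   list(model = "two_component", n_molecules = 5, tau_diff1 = 1e-3,
#'        tau_diff2 = 5e-3, alpha = 0.8, f_fast = 0.6),
#'   noise_sd = 0.02, n_curves = 1, seed = 7)[[1]]
#' fit <- fcs_fit(curve)
#' coef(fit)
#' @export
fcs_fit <- function(curve,
                    model = c("two_component", "one_component", "anomalous"),
                    s = .default_structure_factor,
                    chi2 = c("reduced", "raw"),
                    exponent = c("standard", "printed"),
                    form = c("sum", "literal_product"),
                    n_starts = 3L) {
  model <- match.arg(model)
  chi2_mode <- match.arg(chi2)
  exponent <- match.arg(exponent)
  form <- match.arg(form)
  stopifnot(inherits(curve, "acf_curve"))
  lags <- curve$lags; g <- curve$g
  if (length(lags) < 20) {
    stop("curve must have at least 20 lag points", call. = FALSE)
  }
  if (log10(max(lags) / min(lags)) < 3) {
    stop("lag grid must span at least 3 decades", call. = FALSE)
  }
  w <- if (!is.null(curve$g_se)) 1 / curve$g_se^2 else rep(1, length(g))
  sw <- sqrt(w)

  # --- data-driven initialization ------------------------------------
  first_decade <- lags <= min(lags) * 10
  plateau <- mean(g[first_decade])
  below <- which(g < plateau / 2)
  tau0 <- if (length(below)) lags[below[1]] else exp(mean(log(range(lags))))
  tau0 <- min(max(tau0, 1.1e-6), 0.9)
  n0 <- if (g[1] > 0) 1 / g[1] else 1
  n0 <- min(max(n0, 1.1e-3), 9e3)

  lb_n <- log(1e-3); ub_n <- log(1e4)
  lb_t <- log(1e-6); ub_t <- log(1)

  eval_model <- switch(model,
    one_component = function(p, tau) {
      acf_one_component(tau, exp(p[1]), exp(p[2]), s = s)
    },
    anomalous = function(p, tau) {
      acf_anomalous(tau, exp(p[1]), exp(p[2]), alpha = p[3],
                    g_inf = p[4], s = s, exponent = exponent)
    },
    two_component = function(p, tau) {
      tau1 <- exp(p[2]); tau2 <- tau1 * (1 + exp(p[3]))
      acf_two_component(tau, exp(p[1]), tau1, tau2, alpha = p[4],
                        f_fast = p[5], s = s, form = form,
                        exponent = exponent)
    })

  start0 <- switch(model,
    one_component = c(log(n0), log(tau0)),
    anomalous = c(log(n0), log(tau0), 0.9, 0),
    two_component = c(log(n0), log(tau0), log(4), 0.8, 0.5))
  lower <- switch(model,
    one_component = c(lb_n, lb_t),
    anomalous = c(lb_n, lb_t, 0.05, -1),
    two_component = c(lb_n, lb_t, log(0.05), 0.05, 0))
  upper <- switch(model,
    one_component = c(ub_n, ub_t),
    anomalous = c(ub_n, ub_t, 1.5, 1),
    two_component = c(ub_n, ub_t, log(1e4), 1.5, 1))

  # fixed jitter multipliers on the time scale and fraction: cheap,
  # reproducible guard against local minima
  jit <- list(c(0, 0), c(0, log(0.3)), c(0, log(3)))
  starts <- list(start0)
  for (i in seq_len(min(n_starts, length(jit)))) {
    st <- start0
    st[2] <- st[2] + jit[[i]][2]
    if (model == "two_component") st[5] <- c(0.5, 0.3, 0.7)[i]
    starts[[length(starts) + 1]] <- st
  }

  resid_fn <- function(p) sw * (g - eval_model(p, lags))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    ok <- res$info %in% c(1, 2, 3, 4) && all(is.finite(res$par))
    if (!ok) next
    if (is.null(best) || ssr < best$ssr) best <- list(fit = res, ssr = ssr)
  }

  n_par <- length(start0)
  if (is.null(best)) {
    out <- structure(
      list(model = model, coefficients = NULL, chi2 = Inf,
           chi2_mode = chi2_mode, converged = FALSE,
           qc_status = "fail", qc_reasons = "no_convergence",
           curve = curve, fitted = NULL, weights = w,
           n_obs = length(g), n_par = n_par, s = s,
           form = form, exponent = exponent),
      class = "fcs_fit")
    return(out)
  }
  p <- best$fit$par
  cf <- switch(model,
    one_component = c(n_molecules = exp(p[1]), tau_diff = exp(p[2]), s = s),
    anomalous = c(n_molecules = exp(p[1]), tau_diff = exp(p[2]),
                  alpha = p[3], g_inf = p[4], s = s),
    two_component = c(n_molecules = exp(p[1]), tau_diff1 = exp(p[2]),
                      tau_diff2 = exp(p[2]) * (1 + exp(p[3])),
                      alpha = p[4], f_fast = p[5], s = s))
  chi2_val <- if (chi2_mode == "reduced") {
    best$ssr / max(length(g) - n_par, 1)
  } else best$ssr
  structure(
    list(model = model, coefficients = cf, chi2 = chi2_val,
         chi2_mode = chi2_mode, converged = TRUE,
         qc_status = "pending", qc_reasons = character(0),
         curve = curve, fitted = eval_model(p, lags), weights = w,
         n_obs = length(g), n_par = n_par, s = s,
         form = form, exponent = exponent),
    class = "fcs_fit")
}

#' @export
coef.fcs_fit <- function(object, ...) object$coefficients

#' @export
fitted.fcs_fit <- function(object, ...) object$fitted

#' @export
residuals.fcs_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  if (!object$converged) return(NULL)
  r <- object$curve$g - object$fitted
  if (type == "weighted") r * sqrt(object$weights) else r
}

#' Predict G(tau) from a fitted FCS model
#'
#' @param object An `"fcs_fit"`.
#' @param lags Lag times (seconds) to evaluate at; defaults to the
#'   fitted curve's grid.
#' @param ... Unused.
#' @export
predict.fcs_fit <- function(object, lags = object$curve$lags, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  cf <- object$coefficients
  switch(object$model,
    one_component = acf_one_component(lags, cf[["n_molecules"]],
                                      cf[["tau_diff"]], s = object$s),
    anomalous = acf_anomalous(lags, cf[["n_molecules"]], cf[["tau_diff"]],
                              alpha = cf[["alpha"]], g_inf = cf[["g_inf"]],
                              s = object$s, exponent = object$exponent),
    two_component = acf_two_component(
      lags, cf[["n_molecules"]], cf[["tau_diff1"]], cf[["tau_diff2"]],
      alpha = cf[["alpha"]], f_fast = cf[["f_fast"]], s = object$s,
      form = object$form, exponent = object$exponent))
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: %s model%s\n", x$model,
              if (x$converged) "" else " (NOT converged)"))
  if (x$converged) {
    cf <- x$coefficients
    if (x$model == "two_component") {
      cat(sprintf(
        "  N = %.3g, tau_diff1 = %.3g ms, tau_diff2 = %.3g ms,\n",
        cf[["n_molecules"]], cf[["tau_diff1"]] * 1e3,
        cf[["tau_diff2"]] * 1e3))
      cat(sprintf("  alpha = %.3g, F_fast = %.3g\n",
                  cf[["alpha"]], cf[["f_fast"]]))
    } else {
      cat(sprintf("  N = %.3g, tau_diff = %.3g ms\n",
                  cf[["n_molecules"]], cf[["tau_diff"]] * 1e3))
      if (x$model == "anomalous") {
        cat(sprintf("  alpha = %.3g, G(inf) = %.3g\n",
                    cf[["alpha"]], cf[["g_inf"]]))
      }
    }
    cat(sprintf("  chi2 (%s) = %.4g\n", x$chi2_mode, x$chi2))
  }
  cat(sprintf("  QC: %s%s\n", x$qc_status,
              if (length(x$qc_reasons))
                paste0(" [", paste(x$qc_reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    r <- residuals(object)
    cat(sprintf("  residuals: rms %.3g over %d lags (%.3g-%.3g s)\n",
                sqrt(mean(r^2)), object$n_obs,
                min(object$curve$lags), max(object$curve$lags)))
  }
  invisible(object)
}

#' @export
plot.fcs_fit <- function(x, ...) {
  plot(x$curve$lags, x$curve$g, log = "x", xlab = "lag (s)",
       ylab = expression(G(tau)), ...)
  if (x$converged) {
    grid_lags <- exp(seq(log(min(x$curve$lags)), log(max(x$curve$lags)),
                         length.out = 200))
    lines(grid_lags, predict(x, grid_lags), col = 2, lwd = 2)
    legend("topright", c("data", x$model), pch = c(1, NA),
           lty = c(NA, 1), col = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Simulate noisy curves from a fitted FCS model
#'
#' Draws replicate autocorrelation curves from the fitted parameters
#' using the analytic generator [simulate_acf()].
#'
#' @param object A converged `"fcs_fit"`.
#' @param nsim Number of curves.
#' @param seed Integer seed.
#' @param noise_sd Relative noise level; default 0.02.
#' @param ... Unused.
#' @export
simulate.fcs_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.02, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  cf <- as.list(object$coefficients)
  params <- c(list(model = object$model), cf[setdiff(names(cf), "s")])
  simulate_acf(params, noise_sd = noise_sd, n_curves = nsim, seed = seed,
               lag_range = range(object$curve$lags), s = object$s)
}

#' Choose between one- and two-component fits by chi-square
#'
#' Returns the fit with the lower chi-square. Ties (within 1e-9
#' relative) go to the one-component model, the more parsimonious
#' description. If only one fit converged, that one is returned.
#'
#' @param fit_1c,fit_2c `"fcs_fit"` objects on the same curve.
#' @return The selected `"fcs_fit"`.
#' @export
select_model <- function(fit_1c, fit_2c) {
  stopifnot(inherits(fit_1c, "fcs_fit"), inherits(fit_2c, "fcs_fit"))
  if (!fit_1c$converged && !fit_2c$converged) {
    stop("neither fit converged", call. = FALSE)
  }
  if (!fit_1c$converged) return(fit_2c)
  if (!fit_2c$converged) return(fit_1c)
  denom <- max(abs(fit_1c$chi2), abs(fit_2c$chi2), .Machine$double.xmin)
  if (abs(fit_1c$chi2 - fit_2c$chi2) / denom <= 1e-9) return(fit_1c)
  if (fit_2c$chi2 < fit_1c$chi2) fit_2c else fit_1c
}

#' Default quality-control thresholds for FCS fits
#'
#' Measurements are rejected when the fast diffusion time falls below
#' `tau1_min` (signal dominated by free dye-labeled RNA), exceeds
#' `tau1_max` (aggregation), when the anomaly exponent falls below
#' `alpha_min`, or when the chi-square exceeds `chi2_max`. Fits where
#' a second component was requested but not identified are also
#' rejected.
#'
#' @param tau1_min,tau1_max Fast-component diffusion time bounds,
#'   seconds; defaults 0.5 ms and 10 ms.
#' @param alpha_min Minimum anomaly exponent; default 0.3.
#' @param chi2_max Maximum chi-square; default 30.
#' @return A named list of thresholds for [qc_filter()].
#' @export
qc_thresholds <- function(tau1_min = 5e-4, tau1_max = 1e-2,
                          alpha_min = 0.3, chi2_max = 30) {
  list(tau1_min = tau1_min, tau1_max = tau1_max,
       alpha_min = alpha_min, chi2_max = chi2_max)
}

#' Apply quality-control filters to a fitted curve
#'
#' Pure function: stamps `qc_status` and the exhaustive list of
#' `qc_reasons` onto the fit without altering any parameter. All
#' violated thresholds are reported, not just the first.
#'
#' @param fit An `"fcs_fit"`.
#' @param thresholds See [qc_thresholds()].
#' @param requested_model The model the analysis asked for; when
#'   `"two_component"` and the fit in hand is not two-component (e.g.
#'   after [select_model()] preferred the simpler model), the reason
#'   `no_second_component` is recorded.
#' @return The fit with `qc_status` (`"pass"`/`"fail"`) and
#'   `qc_reasons` (subset of `free_rna`, `aggregation`, `low_alpha`,
#'   `high_chi2`, `no_second_component`, `no_convergence`).
#' @export
qc_filter <- function(fit, thresholds = qc_thresholds(),
                      requested_model = "two_component") {
  stopifnot(inherits(fit, "fcs_fit"))
  reasons <- character(0)
  if (!fit$converged) {
    reasons <- "no_convergence"
  } else {
    cf <- fit$coefficients
    tau1 <- if ("tau_diff1" %in% names(cf)) cf[["tau_diff1"]]
            else cf[["tau_diff"]]
    if (tau1 < thresholds$tau1_min) reasons <- c(reasons, "free_rna")
    if (tau1 > thresholds$tau1_max) reasons <- c(reasons, "aggregation")
    if ("alpha" %in% names(cf) && cf[["alpha"]] < thresholds$alpha_min) {
      reasons <- c(reasons, "low_alpha")
    }
    if (fit$chi2 > thresholds$chi2_max) reasons <- c(reasons, "high_chi2")
    if (identical(requested_model, "two_component") &&
        fit$model != "two_component") {
      reasons <- c(reasons, "no_second_component")
    }
  }
  fit$qc_status <- if (length(reasons)) "fail" else "pass"
  fit$qc_reasons <- reasons
  fit
}

#' Summarize QC outcomes per experimental condition
#'
#' Counts accepted curves per condition and flags conditions with too
#' few passes to report (the analysis convention is at least 20
#' accepted concentration values per condition).
#'
#' @param fits List of `"fcs_fit"` objects that have been through
#'   [qc_filter()].
#' @param conditions Character vector of condition labels, one per
#'   fit; defaults to each curve's `meta$condition` (or `"all"`).
#' @param min_pass Minimum accepted curves per condition; default 20.
#' @return A data frame with one row per condition: `condition`,
#'   `n_total`, `n_pass`, `accepted` (logical), `flag`
#'   (`"ok"`/`"insufficient_n"`), and mean +/- SEM of the fitted
#'   molecule number over passing fits (`mean_n`, `sem_n`).
#' @export
condition_summary <- function(fits, conditions = NULL, min_pass = 20L) {
  if (length(fits) == 0) {
    return(data.frame(condition = "all", n_total = 0L, n_pass = 0L,
                      accepted = FALSE, flag = "insufficient_n",
                      mean_n = NA_real_, sem_n = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (is.null(conditions)) {
    conditions <- vapply(fits, function(f) {
      cnd <- f$curve$meta$condition
      if (is.null(cnd)) "all" else as.character(cnd)
    }, character(1))
  }
  stopifnot(length(conditions) == length(fits))
  out <- lapply(unique(conditions), function(cnd) {
    sel <- fits[conditions == cnd]
    pass <- Filter(function(f) identical(f$qc_status, "pass"), sel)
    n_vals <- vapply(pass, function(f) f$coefficients[["n_molecules"]],
                     numeric(1))
    data.frame(
      condition = cnd, n_total = length(sel), n_pass = length(pass),
      accepted = length(pass) >= min_pass,
      flag = if (length(pass) >= min_pass) "ok" else "insufficient_n",
      mean_n = if (length(n_vals)) mean(n_vals) else NA_real_,
      sem_n = if (length(n_vals) > 1) sd(n_vals) / sqrt(length(n_vals))
              else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
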