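#' Temperature-correct a diffusion coefficient
#'
#' Literature diffusion coefficients for calibration dyes are usually
#' reported at 25 degrees C; FCS experiments in live cells run at 37.
#' The Stokes-Einstein relation gives
#' D(t) = D(25C) * (t + 273.15) / eta(t) * k, with k = 2.985e-6
#' Pa s / K chosen so the correction is the identity at 25 degrees C
#' (k * 298.15 K = 8.901e-4 Pa s = eta(25C)).
#'
#' @param d25 Diffusion coefficient at 25 degrees C, cm^2/s.
#' @param t Target temperature in degrees C (0-60).
#' @param constants Physical constants; see [fcs_constants()].
#' @return Diffusion coefficient at `t` in cm^2/s.
#' @examples
#' temp_correct_diffusion(3.88e-6, 37)  # -> 5.20e-6 cm^2/s
#' @export
temp_correct_diffusion <- function(d25, t, constants = fcs_constants()) {
  if (any(!is.finite(d25)) || any(d25 <= 0)) {
    stop("d25 must be > 0", call. = FALSE)
  }
  eta_t <- constants$eta(t)  # errors outside [0, 60] C
  d25 * (t + 273.15) / eta_t * constants$stokes_constant
}

#' Lateral waist of the confocal volume
#'
#' omega1 = sqrt(4 * D * tau_diff): the lateral 1/e^2 extension of the
#' Gaussian detection volume, from the known diffusion coefficient of a
#' dye standard and its fitted dwell time.
#'
#' @param d Diffusion coefficient, cm^2/s.
#' @param tau_diff Fitted diffusion time of the standard, seconds.
#' @return Lateral waist in cm.
#' @export
lateral_waist <- function(d, tau_diff) {
  if (any(!is.finite(d)) || any(d <= 0) ||
      any(!is.finite(tau_diff)) || any(tau_diff <= 0)) {
    stop("d and tau_diff must be > 0", call. = FALSE)
  }
  sqrt(4 * d * tau_diff)
}

#' Effective confocal volume
#'
#' V_eff = pi^(3/2) * omega1^3 / s, converted from cm^3 to liters
#' (1 cm^3 = 1e-3 l). This is the detection volume used to convert
#' fitted molecule counts to molar concentrations.
#'
#' @param omega1 Lateral waist in cm.
#' @param s Structure factor in (0, 1).
#' @return Effective volume in liters.
#' @export
effective_volume <- function(omega1, s) {
  if (any(!is.finite(omega1)) || any(omega1 <= 0)) {
    stop("omega1 must be > 0", call. = FALSE)
  }
  .check_structure_factor(s)
  pi^(3 / 2) * omega1^3 / s * 1e-3
}

#' Calibrate the effective confocal volume from dye-standard traces
#'
#' Fits the one-component model to each dye autocorrelation curve with
#' the structure factor fixed, averages the fitted diffusion times,
#' temperature-corrects the dye's literature diffusion coefficient to
#' the measurement temperature, and propagates through
#' [lateral_waist()] and [effective_volume()]. Curves whose fit fails
#' to converge, or that contain non-finite amplitudes, are excluded
#' (with a message); at least 3 surviving curves are required.
#'
#' @param curves List of [acf_curve()] objects measured on the dye
#'   standard.
#' @param dye A dye standard, e.g. `dye_standard("alexa_594")`, or any
#'   list with elements `name` and `d25` (cm^2/s at 25 C).
#' @param t Measurement temperature in degrees C; default 37.
#' @param s Structure factor, fixed during fitting; default 0.17.
#' @param constants Physical constants; see [fcs_constants()].
#' @return An object of class `"focal_volume"` with elements
#'   `structure_factor`, `omega1` (cm), `omega1_um`, `v_eff` (liters),
#'   `v_eff_fl`, `source_tau_diff` (s), `n_calibration_traces`,
#'   `dye`, `temperature`, `d_t` (corrected diffusion coefficient),
#'   and `in_typical_range` (FALSE, with a warning, when V_eff falls
#'   outside the 0.25-0.4 fl range typical of a high-NA confocal
#'   system).
#' @examples
#' curves <- simulate_acf(
#'   list(model = "one_component", n_molecules = 2, tau_diff = 2e-5),
#'   noise_sd = 0, n_curves = 5, seed = 1)
#' calibrate_focal_volume(curves, dye_standard("alexa_594"), t = 37)
#' @export
calibrate_focal_volume <- function(curves, dye, t = 37,
                                   s = .default_structure_factor,
                                   constants = fcs_constants()) {
  if (inherits(curves, "acf_curve")) curves <- list(curves)
  if (length(curves) < 3) {
    stop("calibration requires at least 3 dye curves", call. = FALSE)
  }
  tau_hat <- rep(NA_real_, length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (!inherits(cv, "acf_curve")) {
      stop("curves must be acf_curve objects", call. = FALSE)
    }
    if (any(!is.finite(cv$g))) {
      message("calibration curve ", i, " excluded: non-finite amplitudes")
      next
    }
    fit <- tryCatch(
      fcs_fit(cv, model = "one_component", s = s),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      message("calibration curve ", i, " excluded: fit did not converge")
      next
    }
    tau_hat[i] <- coef(fit)[["tau_diff"]]
  }
  ok <- is.finite(tau_hat)
  if (sum(ok) < 3) {
    stop("fewer than 3 calibration curves survived fitting", call. = FALSE)
  }
  tau_mean <- mean(tau_hat[ok])
  d_t <- temp_correct_diffusion(dye$d25, t, constants)
  omega1 <- lateral_waist(d_t, tau_mean)
  v_eff <- effective_volume(omega1, s)
  v_eff_fl <- v_eff * 1e15
  in_range <- v_eff_fl >= 0.25 && v_eff_fl <= 0.4
  if (!in_range) {
    warning(sprintf(
      "calibrated V_eff = %.3g fl is outside the typical 0.25-0.4 fl range",
      v_eff_fl), call. = FALSE)
  }
  structure(
    list(structure_factor = s,
         omega1 = omega1, omega1_um = omega1 * 1e4,
         v_eff = v_eff, v_eff_fl = v_eff_fl,
         source_tau_diff = tau_mean,
         n_calibration_traces = sum(ok),
         dye = dye$name, temperature = t, d_t = d_t,
         in_typical_range = in_range),
    class = "focal_volume"
  )
}

#' Construct a focal volume directly from known geometry
#'
#' Bypasses dye fitting when the waist is already known (e.g. from a
#' simulation's ground truth).
#'
#' @inheritParams effective_volume
#' @return A `"focal_volume"` object; see [calibrate_focal_volume()].
#' @export
focal_volume <- function(omega1, s = .default_structure_factor) {
  v_eff <- effective_volume(omega1, s)
  structure(
    list(structure_factor = s, omega1 = omega1, omega1_um = omega1 * 1e4,
         v_eff = v_eff, v_eff_fl = v_eff * 1e15,
         source_tau_diff = NA_real_, n_calibration_traces = 0L,
         dye = NA_character_, temperature = NA_real_, d_t = NA_real_,
         in_typical_range = v_eff * 1e15 >= 0.25 && v_eff * 1e15 <= 0.4),
    class = "focal_volume"
  )
}

#' @export
print.focal_volume <- function(x, ...) {
  cat("Confocal effective volume calibration\n")
  if (!is.na(x$dye)) {
    cat(sprintf("  dye: %s at %g C (D = %.3g cm^2/s), %d traces\n",
                x$dye, x$temperature, x$d_t, x$n_calibration_traces))
  }
  cat(sprintf("  structure factor s = %.3g (fixed)\n", x$structure_factor))
  if (!is.na(x$source_tau_diff)) {
    cat(sprintf("  mean tau_diff = %.3g s\n", x$source_tau_diff))
  }
  cat(sprintf("  omega1 = %.3g um; V_eff = %.3g fl%s\n",
              x$omega1_um, x$v_eff_fl,
              if (x$in_typical_range) "" else "  [outside 0.25-0.4 fl]"))
  invisible(x)
}
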