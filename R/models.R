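#' Autocorrelation curve container
#'
#' Bundles one FCS measurement: a grid of lag times, the normalized
#' autocorrelation amplitudes G(tau), and (optionally) per-lag standard
#' errors from sub-trace averaging.
#'
#' @param lags Lag times in seconds; strictly increasing, all > 0.
#' @param g Correlation amplitudes, same length as `lags`; finite.
#' @param g_se Optional per-lag standard error of `g`; same length,
#'   all entries > 0.
#' @param n_traces Number of averaged sub-traces behind this curve.
#' @param trace_duration Total acquisition time in seconds (NA if
#'   unknown, e.g. for model-generated curves).
#' @param meta Free-form list of acquisition labels (cell id,
#'   condition, dose, ...).
#' @return An object of class `"acf_curve"`.
#' @export
acf_curve <- function(lags, g, g_se = NULL, n_traces = 1L,
                      trace_duration = NA_real_, meta = list()) {
  lags <- as.numeric(lags); g <- as.numeric(g)
  if (length(lags) != length(g)) {
    stop("lags and g must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lags)) || any(lags <= 0)) {
    stop("lags must be finite and > 0", call. = FALSE)
  }
  if (any(diff(lags) <= 0)) {
    stop("lags must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(g))) stop("g must be finite", call. = FALSE)
  if (!is.null(g_se)) {
    g_se <- as.numeric(g_se)
    if (length(g_se) != length(g)) {
      stop("g_se must have the same length as g", call. = FALSE)
    }
    if (any(!is.finite(g_se)) || any(g_se <= 0)) {
      stop("g_se entries must be finite and > 0", call. = FALSE)
    }
  }
  structure(
    list(lags = lags, g = g, g_se = g_se, n_traces = as.integer(n_traces),
         trace_duration = trace_duration, meta = meta),
    class = "acf_curve"
  )
}

#' @export
print.acf_curve <- function(x, ...) {
  cat("FCS autocorrelation curve\n")
  cat(sprintf("  %d lags from %.3g to %.3g s\n",
              length(x$lags), min(x$lags), max(x$lags)))
  cat(sprintf("  G(first lag) = %.4g%s\n", x$g[1],
              if (is.null(x$g_se)) "" else " (with per-lag SE)"))
  if (x$n_traces > 1) cat(sprintf("  averaged over %d sub-traces\n", x$n_traces))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.acf_curve <- function(x, ..., log = "x", xlab = "lag (s)",
                           ylab = expression(G(tau))) {
  plot(x$lags, x$g, log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

.check_tau <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("tau must be finite and > 0", call. = FALSE)
  }
  tau
}

.check_structure_factor <- function(s) {
  if (!is.finite(s) || s <= 0 || s >= 1) {
    stop("structure factor s must lie in (0, 1)", call. = FALSE)
  }
  s
}

# free-diffusion kernel: unit-amplitude single-species 3D term
.kernel_free <- function(tau, tau_diff, s) {
  x <- tau / tau_diff
  1 / ((1 + x) * sqrt(1 + s^2 * x))
}

# anomalous kernel. "standard" raises tau/tau_diff to alpha inside both
# factors; "printed" raises the whole factors to alpha (an alternative
# typeset form of the same model found in parts of the FCS literature).
.kernel_anomalous <- function(tau, tau_diff, alpha, s,
                              exponent = c("standard", "printed")) {
  exponent <- match.arg(exponent)
  x <- tau / tau_diff
  if (exponent == "standard") {
    xa <- x^alpha
    1 / ((1 + xa) * sqrt(1 + s^2 * xa))
  } else {
    1 / ((1 + x)^alpha * (sqrt(1 + s^2 * x))^alpha)
  }
}

#' One-component 3D diffusion autocorrelation model
#'
#' G(tau) = (1/N) / ((1 + tau/tau_diff) * sqrt(1 + s^2 tau/tau_diff)),
#' the autocorrelation of a single freely diffusing species in a 3D
#' Gaussian focal volume with radial/axial ratio `s`. The zero-lag
#' amplitude is 1/N, where N is the mean number of molecules in the
#' effective volume.
#'
#' @param tau Lag times in seconds (> 0); vectorized.
#' @param n_molecules Mean molecules in the focal volume, > 0.
#' @param tau_diff Diffusion (dwell) time in seconds, > 0.
#' @param s Structure factor in (0, 1); default 0.17.
#' @return G(tau), dimensionless, same length as `tau`.
#' @examples
#' acf_one_component(1e-3, n_molecules = 5, tau_diff = 1e-3)
#' @export
acf_one_component <- function(tau, n_molecules, tau_diff,
                              s = .default_structure_factor) {
  .check_tau(tau)
  .check_structure_factor(s)
  if (!is.finite(n_molecules) || n_molecules <= 0) {
    stop("n_molecules must be > 0", call. = FALSE)
  }
  if (!is.finite(tau_diff) || tau_diff <= 0) {
    stop("tau_diff must be > 0", call. = FALSE)
  }
  (1 / n_molecules) * .kernel_free(tau, tau_diff, s)
}

#' Anomalous (subdiffusive) 3D autocorrelation model
#'
#' Single-species model in which the mean-squared displacement grows as
#' t^alpha; alpha < 1 describes hindered (crowded or binding-limited)
#' motion, alpha = 1 recovers free diffusion. An additive offset
#' `g_inf` absorbs residual long-lag correlation.
#'
#' @inheritParams acf_one_component
#' @param alpha Anomaly exponent in (0, 1.5].
#' @param g_inf Additive offset G(infinity); default 0.
#' @param exponent Where the anomaly exponent is applied: `"standard"`
#'   raises tau/tau_diff to alpha inside both factors (the conventional
#'   anomalous-diffusion ACF); `"printed"` raises the complete
#'   one-component factors to alpha instead. Both occur in the
#'   literature as typeset variants.
#' @return G(tau), dimensionless.
#' @export
acf_anomalous <- function(tau, n_molecules, tau_diff, alpha, g_inf = 0,
                          s = .default_structure_factor,
                          exponent = c("standard", "printed")) {
  exponent <- match.arg(exponent)
  .check_tau(tau)
  .check_structure_factor(s)
  if (!is.finite(n_molecules) || n_molecules <= 0) {
    stop("n_molecules must be > 0", call. = FALSE)
  }
  if (!is.finite(tau_diff) || tau_diff <= 0) {
    stop("tau_diff must be > 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1.5) {
    stop("alpha must lie in (0, 1.5]", call. = FALSE)
  }
  (1 / n_molecules) * .kernel_anomalous(tau, tau_diff, alpha, s, exponent) +
    g_inf
}

#' Two-component diffusion autocorrelation model
#'
#' Mixture of a fast freely diffusing fraction `f_fast` and a slow,
#' anomalously diffusing fraction `1 - f_fast` — the model of choice
#' for DNA-binding proteins in nuclei, where a biphasic decay reflects
#' free molecules plus chromatin-bound ones. The default `form = "sum"`
#' is the standard additive mixture:
#'
#' G(tau) = (1/N) * (F_fast * g1(tau; tau_diff1)
#'                   + (1 - F_fast) * g2(tau; tau_diff2, alpha))
#'
#' `form = "literal_product"` instead multiplies the two bracketed
#' terms. That form makes the zero-lag amplitude
#' F_fast*(1-F_fast)/N rather than 1/N, contradicting the meaning of N
#' as a molecule count; it is retained only for fidelity checks against
#' that typeset variant.
#'
#' @inheritParams acf_anomalous
#' @param tau_diff1 Fast-component diffusion time, seconds; must be
#'   less than `tau_diff2`.
#' @param tau_diff2 Slow-component diffusion time, seconds.
#' @param f_fast Fraction of molecules in the fast component, in [0,1].
#' @param form `"sum"` (default) or `"literal_product"`; see Details.
#' @return G(tau), dimensionless.
#' @examples
#' acf_two_component(1e-3, n_molecules = 5, tau_diff1 = 1e-3,
#'                   tau_diff2 = 5e-3, alpha = 0.8, f_fast = 0.6)
#' @export
acf_two_component <- function(tau, n_molecules, tau_diff1, tau_diff2,
                              alpha, f_fast,
                              s = .default_structure_factor,
                              form = c("sum", "literal_product"),
                              exponent = c("standard", "printed")) {
  form <- match.arg(form)
  exponent <- match.arg(exponent)
  .check_tau(tau)
  .check_structure_factor(s)
  if (!is.finite(n_molecules) || n_molecules <= 0) {
    stop("n_molecules must be > 0", call. = FALSE)
  }
  if (!is.finite(tau_diff1) || tau_diff1 <= 0 ||
      !is.finite(tau_diff2) || tau_diff2 <= 0) {
    stop("diffusion times must be > 0", call. = FALSE)
  }
  if (tau_diff1 >= tau_diff2) {
    stop("tau_diff1 must be smaller than tau_diff2 ",
         "(fast component first)", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1.5) {
    stop("alpha must lie in (0, 1.5]", call. = FALSE)
  }
  if (!is.finite(f_fast) || f_fast < 0 || f_fast > 1) {
    stop("f_fast must lie in [0, 1]", call. = FALSE)
  }
  g1 <- .kernel_free(tau, tau_diff1, s)
  g2 <- .kernel_anomalous(tau, tau_diff2, alpha, s, exponent)
  if (form == "sum") {
    (1 / n_molecules) * (f_fast * g1 + (1 - f_fast) * g2)
  } else {
    (1 / n_molecules) * (f_fast * g1) * ((1 - f_fast) * g2)
  }
}
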