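#' Photon-count trace container
#'
#' A binned photon-count time series as produced by a counting detector
#' — the raw material the correlator turns into an autocorrelation
#' curve.
#'
#' @param counts Non-negative integer counts per bin.
#' @param bin_time Bin width in seconds.
#' @param meta Free-form list of acquisition labels.
#' @return An object of class `"photon_trace"` with fields `counts`,
#'   `bin_time`, `duration`, `meta`.
#' @export
photon_trace <- function(counts, bin_time, meta = list()) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty trace", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(bin_time) || bin_time <= 0) {
    stop("bin_time must be > 0", call. = FALSE)
  }
  structure(
    list(counts = counts, bin_time = bin_time,
         duration = length(counts) * bin_time, meta = meta),
    class = "photon_trace"
  )
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf(
    "Photon trace: %d bins x %.3g s = %.3g s, mean %.3g counts/bin\n",
    length(x$counts), x$bin_time, x$duration, mean(x$counts)))
  invisible(x)
}

# correlation estimator at one integer lag on a count series.
# plain:     <dF(t) dF(t+k)> / mu^2 with mu the series mean
# symmetric: <F(t) F(t+k)> / (mean_left * mean_right) - 1, which
#            cancels slow drift in the two shifted segments
.acf_at_lag <- function(counts, k, normalization = "plain") {
  n <- length(counts)
  left <- counts[seq_len(n - k)]
  right <- counts[seq_len(n - k) + k]
  if (normalization == "plain") {
    mu <- mean(counts)
    if (mu == 0) stop("zero mean intensity: normalization undefined",
                      call. = FALSE)
    mean((left - mu) * (right - mu)) / mu^2
  } else {
    ml <- mean(left); mr <- mean(right)
    if (ml == 0 || mr == 0) {
      stop("zero mean intensity: normalization undefined", call. = FALSE)
    }
    mean(left * right) / (ml * mr) - 1
  }
}

#' Direct (linear-lag) autocorrelation of a photon trace
#'
#' Computes G(tau_k) = <dF(t) dF(t+tau_k)> / <F>^2 by the O(N*K)
#' definition on a linear lag grid of integer bin multiples. Serves as
#' the reference estimator that [acf_multitau()] is checked against;
#' use it on short traces only.
#'
#' @param trace A [photon_trace()].
#' @param max_lag Largest lag in seconds; must be < duration/2.
#' @param normalization `"plain"` (global-mean, matching the
#'   definition above) or `"symmetric"` (per-segment means).
#' @return An [acf_curve()] on the linear lag grid (lag 0 excluded:
#'   it is shot-noise dominated).
#' @export
acf_direct <- function(trace, max_lag,
                       normalization = c("plain", "symmetric")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(trace, "photon_trace"))
  if (!is.finite(max_lag) || max_lag <= 0 || max_lag >= trace$duration / 2) {
    stop("max_lag must be positive and < duration/2", call. = FALSE)
  }
  k_max <- floor(max_lag / trace$bin_time)
  if (k_max < 1) stop("max_lag shorter than one bin", call. = FALSE)
  g <- vapply(seq_len(k_max), function(k) {
    .acf_at_lag(trace$counts, k, normalization)
  }, numeric(1))
  acf_curve(seq_len(k_max) * trace$bin_time, g,
            trace_duration = trace$duration, meta = trace$meta)
}

#' Multi-tau autocorrelation of a photon trace
#'
#' Quasi-logarithmic correlator: the first `m` lags are computed at the
#' native bin width, then the series is repeatedly coarsened by a
#' factor of 2 and lags m/2+1 .. m computed at each coarser width.
#' This covers many decades of lag time at O(N log N) cost, the scheme
#' hardware correlators implement.
#'
#' @inheritParams acf_direct
#' @param m Lags per octave-doubling level; even, >= 8. Default 16.
#' @param normalization `"symmetric"` (default; per-segment means,
#'   suppressing drift bias) or `"plain"` (global mean, identical to
#'   [acf_direct()] on the uncoarsened lags).
#' @return An [acf_curve()] on the quasi-logarithmic lag grid.
#' @export
acf_multitau <- function(trace, max_lag, m = 16L,
                         normalization = c("symmetric", "plain")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(trace, "photon_trace"))
  m <- as.integer(m)
  if (m < 8L || m %% 2L != 0L) stop("m must be even and >= 8", call. = FALSE)
  if (!is.finite(max_lag) || max_lag <= 0 || max_lag >= trace$duration / 2) {
    stop("max_lag must be positive and < duration/2", call. = FALSE)
  }
  counts <- trace$counts
  if (mean(counts) == 0) {
    stop("zero mean intensity: normalization undefined", call. = FALSE)
  }
  width <- 1L          # current bin width in native bins
  lags <- numeric(0); g <- numeric(0)
  ks <- seq_len(m)     # level-0 lags
  repeat {
    for (k in ks) {
      lag_s <- k * width * trace$bin_time
      if (lag_s > max_lag) break
      if (k >= length(counts)) break
      lags <- c(lags, lag_s)
      g <- c(g, .acf_at_lag(counts, k, normalization))
    }
    # coarsen by 2 for the next level
    n2 <- floor(length(counts) / 2)
    if (n2 < m + 2L) break
    counts <- counts[seq_len(2 * n2)]
    counts <- counts[c(TRUE, FALSE)] + counts[c(FALSE, TRUE)]
    width <- width * 2L
    ks <- seq.int(m / 2 + 1L, m)
    if (ks[1] * width * trace$bin_time > max_lag) break
  }
  ord <- order(lags)
  acf_curve(lags[ord], g[ord], trace_duration = trace$duration,
            meta = trace$meta)
}

#' Segment a trace and average per-segment correlations
#'
#' Splits a long measurement into equal sub-traces, correlates each,
#' and returns the per-lag mean with the standard error of the mean as
#' `g_se` — mirroring the acquisition convention of recording ten 10-s
#' traces per measurement point and averaging them.
#'
#' @inheritParams acf_multitau
#' @param n_segments Number of equal sub-traces; default 10.
#' @param correlator `"multitau"` (default) or `"direct"`.
#' @param max_lag Largest lag in seconds; default one tenth of the
#'   segment duration.
#' @return An [acf_curve()] with `g_se` and `n_traces = n_segments`.
#' @export
acf_segment_average <- function(trace, n_segments = 10L,
                                correlator = c("multitau", "direct"),
                                max_lag = NULL, m = 16L,
                                normalization = c("symmetric", "plain")) {
  correlator <- match.arg(correlator)
  normalization <- match.arg(normalization)
  stopifnot(inherits(trace, "photon_trace"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be >= 2", call. = FALSE)
  seg_len <- floor(length(trace$counts) / n_segments)
  if (seg_len < 100L) {
    stop("segments shorter than 100 bins; use fewer segments or a ",
         "longer trace", call. = FALSE)
  }
  seg_dur <- seg_len * trace$bin_time
  if (is.null(max_lag)) max_lag <- seg_dur / 10
  curves <- lapply(seq_len(n_segments), function(i) {
    seg <- photon_trace(
      trace$counts[((i - 1) * seg_len + 1):(i * seg_len)],
      trace$bin_time)
    if (correlator == "multitau") {
      acf_multitau(seg, max_lag = max_lag, m = m,
                   normalization = normalization)
    } else {
      acf_direct(seg, max_lag = max_lag,
                 normalization = if (normalization == "plain")
                   "plain" else "symmetric")
    }
  })
  gmat <- vapply(curves, function(cv) cv$g, numeric(length(curves[[1]]$g)))
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = 1)
  g_mean <- rowMeans(gmat)
  g_se <- apply(gmat, 1, sd) / sqrt(n_segments)
  # guard against exactly-zero SEs (identical segments) so the SE can
  # always serve as a fitting weight
  se_floor <- max(g_se, 1e-12) * 1e-6
  g_se <- pmax(g_se, se_floor)
  acf_curve(curves[[1]]$lags, g_mean, g_se = g_se,
            n_traces = n_segments, trace_duration = trace$duration,
            meta = trace$meta)
}
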