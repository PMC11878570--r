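#' Two-channel droplet well container
#'
#' Per-droplet fluorescence amplitudes from a droplet digital PCR
#' (ddPCR) run. The HEX channel reports a reference amplicon adjacent
#' to the cut site; the FAM channel reports the amplicon spanning the
#' cut site, which is lost when an unrepaired double-strand break (or
#' chromosome loss) destroys the template.
#'
#' @param hex_amplitude,fam_amplitude Per-droplet fluorescence
#'   amplitudes, equal lengths.
#' @param well_id Well label.
#' @param is_reference TRUE for untreated control wells used to set
#'   thresholds.
#' @return An object of class `"droplet_well"`.
#' @export
droplet_well <- function(hex_amplitude, fam_amplitude, well_id = "A01",
                         is_reference = FALSE) {
  hex_amplitude <- as.numeric(hex_amplitude)
  fam_amplitude <- as.numeric(fam_amplitude)
  if (length(hex_amplitude) != length(fam_amplitude)) {
    stop("channel amplitude vectors must have equal length", call. = FALSE)
  }
  if (length(hex_amplitude) < 1) stop("no droplets", call. = FALSE)
  structure(
    list(hex_amplitude = hex_amplitude, fam_amplitude = fam_amplitude,
         well_id = well_id, is_reference = isTRUE(is_reference),
         n_droplets = length(hex_amplitude)),
    class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("Droplet well %s: %d droplets%s\n", x$well_id,
              x$n_droplets, if (x$is_reference) " (reference)" else ""))
  invisible(x)
}

# classify one channel of pooled reference amplitudes into
# negative/positive clusters; returns the threshold between them
.channel_threshold <- function(amps, k) {
  km <- tryCatch(
    suppressWarnings(kmeans(amps, centers = 2, nstart = 5)),
    error = function(e) NULL)
  fallback <- function() {
    warning("reference channel looks unimodal; threshold set to ",
            "mean + k*SD", call. = FALSE)
    mean(amps) + k * sd(amps)
  }
  if (is.null(km)) return(fallback())
  lo <- which.min(km$centers); hi <- which.max(km$centers)
  neg <- amps[km$cluster == lo]; pos <- amps[km$cluster == hi]
  if (length(neg) < 2 || length(pos) < 2) return(fallback())
  sep <- (mean(pos) - mean(neg)) / (sd(neg) + sd(pos) + 1e-12)
  if (!is.finite(sep) || sep < 2) return(fallback())
  edge_neg <- mean(neg) + k * sd(neg)   # negative-cluster upper edge
  edge_pos <- mean(pos) - k * sd(pos)   # positive-cluster lower edge
  (edge_neg + edge_pos) / 2
}

#' Set droplet thresholds from untreated reference wells
#'
#' Per channel, droplets in the pooled reference wells are split into
#' a negative and a positive cluster by two-means clustering; the
#' threshold is the midpoint between the negative cluster's upper edge
#' (mean + k*SD) and the positive cluster's lower edge (mean - k*SD).
#' When a channel has no resolvable second cluster the threshold falls
#' back to mean + k*SD of the whole channel, with a warning.
#'
#' @param reference_wells A [droplet_well()] or list of them (at
#'   least one).
#' @param k SD multiplier defining the cluster edges; default 5.
#' @return A list with `hex` and `fam` thresholds (amplitude units).
#' @export
droplet_thresholds <- function(reference_wells, k = 5) {
  if (inherits(reference_wells, "droplet_well")) {
    reference_wells <- list(reference_wells)
  }
  if (length(reference_wells) < 1) {
    stop("at least one reference well is required", call. = FALSE)
  }
  hex <- unlist(lapply(reference_wells, function(w) w$hex_amplitude))
  fam <- unlist(lapply(reference_wells, function(w) w$fam_amplitude))
  list(hex = .channel_threshold(hex, k), fam = .channel_threshold(fam, k))
}

#' Quantify double-strand breaks in a droplet well
#'
#' Counts positive droplets per channel against the thresholds and
#' computes %DSB = 100 * (1 - [FAM]/[HEX]). In `"poisson"` mode
#' (default) the channel concentrations are the Poisson-corrected
#' copies per droplet, lambda = -ln(1 - positives/n), which is what a
#' droplet reader reports; `"raw_counts"` uses the positive fractions
#' directly and is biased at high occupancy (provided for sensitivity
#' analysis). Negative %DSB values arising from noise are clamped to 0
#' with a warning, never silently.
#'
#' @param well A [droplet_well()].
#' @param thresholds Output of [droplet_thresholds()].
#' @param mode `"poisson"` (default) or `"raw_counts"`.
#' @param min_droplets Minimum droplets for quantification; default
#'   1000.
#' @param n_boot Bootstrap replicates for a percentile confidence
#'   interval on %DSB; 0 (default) skips the bootstrap.
#' @param conf Confidence level for the bootstrap interval.
#' @return An object of class `"dsb_result"`: `well_id`,
#'   `hex_positive`, `fam_positive`, `n_droplets`, `hex_conc`,
#'   `fam_conc` (copies/droplet), `pct_dsb`, `mode`, and optionally
#'   `ci` (length-2 numeric).
#' @export
quantify_droplets <- function(well, thresholds,
                              mode = c("poisson", "raw_counts"),
                              min_droplets = 1000L, n_boot = 0L,
                              conf = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(well, "droplet_well"))
  n <- well$n_droplets
  if (n < min_droplets) {
    stop("well has fewer than ", min_droplets, " droplets", call. = FALSE)
  }
  hex_pos <- sum(well$hex_amplitude > thresholds$hex)
  fam_pos <- sum(well$fam_amplitude > thresholds$fam)
  if (hex_pos == 0) {
    stop("no HEX-positive droplets: %DSB undefined", call. = FALSE)
  }
  conc <- function(pos) {
    p <- pos / n
    if (mode == "poisson") {
      if (p >= 1) p <- (n - 0.5) / n  # saturated channel guard
      -log(1 - p)
    } else p
  }
  hex_c <- conc(hex_pos); fam_c <- conc(fam_pos)
  if (fam_c > hex_c) {
    warning("FAM concentration exceeds HEX: %DSB clamped to 0",
            call. = FALSE)
  }
  pct <- 100 * (1 - fam_c / hex_c)
  pct <- min(max(pct, 0), 100)
  ci <- NULL
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      hp <- sum(well$hex_amplitude[idx] > thresholds$hex)
      fp <- sum(well$fam_amplitude[idx] > thresholds$fam)
      if (hp == 0) return(NA_real_)
      min(max(100 * (1 - conc(fp) / conc(hp)), 0), 100)
    }, numeric(1))
    ci <- unname(quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE))
  }
  structure(
    list(well_id = well$well_id, hex_positive = hex_pos,
         fam_positive = fam_pos, n_droplets = n,
         hex_conc = hex_c, fam_conc = fam_c, pct_dsb = pct,
         mode = mode, ci = ci),
    class = "dsb_result")
}

#' @export
print.dsb_result <- function(x, ...) {
  cat(sprintf("ddPCR well %s (%s mode): %d droplets\n",
              x$well_id, x$mode, x$n_droplets))
  cat(sprintf("  HEX+ %d (lambda %.3g), FAM+ %d (lambda %.3g)\n",
              x$hex_positive, x$hex_conc, x$fam_positive, x$fam_conc))
  cat(sprintf("  %%DSB = %.1f%s\n", x$pct_dsb,
              if (!is.null(x$ci))
                sprintf(" (CI %.1f-%.1f)", x$ci[1], x$ci[2]) else ""))
  invisible(x)
}

#' Quantify a batch of droplet wells
#'
#' Sets thresholds from the wells flagged `is_reference` and
#' quantifies every well against them.
#'
#' @param wells List of [droplet_well()] objects, at least one of
#'   which has `is_reference = TRUE`.
#' @inheritParams quantify_droplets
#' @param k SD multiplier for [droplet_thresholds()].
#' @return Data frame with one row per well: `well_id`,
#'   `is_reference`, `n_droplets`, `hex_positive`, `fam_positive`,
#'   `hex_conc`, `fam_conc`, `pct_dsb`.
#' @export
quantify_droplet_wells <- function(wells, mode = "poisson", k = 5,
                                   min_droplets = 1000L) {
  refs <- Filter(function(w) w$is_reference, wells)
  if (!length(refs)) {
    stop("no reference wells to set thresholds from", call. = FALSE)
  }
  thr <- droplet_thresholds(refs, k = k)
  rows <- lapply(wells, function(w) {
    r <- quantify_droplets(w, thr, mode = mode,
                           min_droplets = min_droplets)
    data.frame(well_id = r$well_id, is_reference = w$is_reference,
               n_droplets = r$n_droplets, hex_positive = r$hex_positive,
               fam_positive = r$fam_positive, hex_conc = r$hex_conc,
               fam_conc = r$fam_conc, pct_dsb = r$pct_dsb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
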