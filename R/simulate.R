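# run expr with a temporarily-seeded RNG, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate autocorrelation curves from an analytic model
#'
#' Fast generator for fitting tests: evaluates the chosen diffusion
#' model on a log-spaced lag grid and adds seeded multiplicative
#' Gaussian noise whose relative magnitude grows with lag, mimicking
#' the variance profile of a real correlator (fewer independent
#' samples at long lags).
#'
#' @param params Named list describing the ground truth:
#'   `model` (`"one_component"`, `"anomalous"`, `"two_component"`),
#'   `n_molecules`, and the model's diffusion parameters
#'   (`tau_diff` or `tau_diff1`/`tau_diff2`, `alpha`, `f_fast`,
#'   `g_inf`).
#' @param noise_sd Relative noise at the shortest lag; the effective
#'   relative SD grows linearly in log-lag up to 3x this value at the
#'   longest lag. 0 returns the exact model values.
#' @param n_curves Number of replicate curves.
#' @param seed Integer seed (RNG state is restored on exit).
#' @param lag_range Lag grid limits in seconds; default 1e-5 to 1.
#' @param points_per_decade Lag grid density; default 40.
#' @param s Structure factor; default 0.17.
#' @return A list of [acf_curve()] objects. Noisy curves carry `g_se`
#'   equal to the true per-lag noise SD; noiseless curves do not.
#' @export
simulate_acf <- function(params, noise_sd = 0.02, n_curves = 1L,
                         seed = NULL, lag_range = c(1e-5, 1),
                         points_per_decade = 40L,
                         s = .default_structure_factor) {
  model <- params$model
  stopifnot(!is.null(model))
  n_dec <- log10(lag_range[2] / lag_range[1])
  lags <- 10^seq(log10(lag_range[1]), log10(lag_range[2]),
                 length.out = max(ceiling(n_dec * points_per_decade), 2))
  g_true <- switch(model,
    one_component = acf_one_component(lags, params$n_molecules,
                                      params$tau_diff, s = s),
    anomalous = acf_anomalous(lags, params$n_molecules, params$tau_diff,
                              alpha = params$alpha,
                              g_inf = params$g_inf %||% 0, s = s),
    two_component = acf_two_component(lags, params$n_molecules,
                                      params$tau_diff1, params$tau_diff2,
                                      alpha = params$alpha,
                                      f_fast = params$f_fast, s = s),
    stop("unknown model '", model, "'", call. = FALSE))
  # lag-dependent noise inflation: 1x at the shortest lag, 3x at the
  # longest (correlator estimates are noisier at long lags)
  lag_factor <- 1 + 2 * (log10(lags) - log10(lags[1])) /
    (log10(lags[length(lags)]) - log10(lags[1]))
  g_scale <- pmax(abs(g_true), max(abs(g_true)) * 1e-3)
  se <- noise_sd * lag_factor * g_scale
  .with_seed(seed, {
    lapply(seq_len(n_curves), function(i) {
      if (noise_sd == 0) {
        acf_curve(lags, g_true, meta = list(replicate = i))
      } else {
        acf_curve(lags, g_true + se * rnorm(length(lags)), g_se = se,
                  meta = list(replicate = i))
      }
    })
  })
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Emulates a counting-mode FCS acquisition: point emitters diffuse
#' through a periodic box containing a 3D Gaussian detection volume,
#' and per-bin photon counts are Poisson draws around the summed
#' detection-profile intensities. Up to two species are supported,
#' matching the two-component analysis model. Anomalous species
#' (alpha < 1) use variance-rescaled Gaussian increments whose
#' mean-squared displacement grows as t^alpha — an approximation to
#' fractional Brownian motion that reproduces the ACF shape, which is
#' the fitting target.
#'
#' The box half-width is `box_multiplier * omega1` laterally and
#' `box_multiplier * omega_z` axially (omega_z = omega1/s): the
#' detection profile at 3 lateral waists is already below 1e-7 of its
#' peak, so a lateral margin beyond 3*omega1 only adds particles that
#' never contribute photons.
#'
#' @param species List of species, each a list with `concentration`
#'   (mol/l), one of `tau_diff` (s) or `d` (cm^2/s), optional `alpha`
#'   (default 1 = Brownian), and `brightness` (counts/s per molecule
#'   at the profile center).
#' @param duration Trace length in seconds.
#' @param bin_time Bin width in seconds.
#' @param omega1 Lateral waist in cm; default 2e-5 (0.2 um).
#' @param s Structure factor; default 0.17.
#' @param box_multiplier Box half-width in waist units; default 3.
#' @param background Background count rate, counts/s; default 0.
#' @param seed Integer seed.
#' @param constants See [fcs_constants()].
#' @return A [photon_trace()]; `meta$truth` records the per-species
#'   expected molecule number in V_eff, concentrations, diffusion
#'   times, and the focal-volume geometry.
#' @examples
#' \donttest{
#' tr <- simulate_fcs_trace(
#'   list(list(concentration = 3e-8, tau_diff = 1e-3,
#'             brightness = 5e4)),
#'   duration = 5, bin_time = 5e-5, seed = 1)
#' }
#' @export
simulate_fcs_trace <- function(species, duration, bin_time,
                               omega1 = 2e-5,
                               s = .default_structure_factor,
                               box_multiplier = 3, background = 0,
                               seed = NULL,
                               constants = fcs_constants()) {
  if (!is.null(species$concentration)) species <- list(species)
  if (length(species) > 2) {
    stop("at most 2 species (the two-component model's limit)",
         call. = FALSE)
  }
  .check_structure_factor(s)
  omega_z <- omega1 / s
  half_x <- box_multiplier * omega1
  half_z <- box_multiplier * omega_z
  v_box_l <- (2 * half_x)^2 * (2 * half_z) * 1e-3  # cm^3 -> liters
  v_eff <- effective_volume(omega1, s)
  n_bins <- round(duration / bin_time)
  if (n_bins < 10) stop("trace too short", call. = FALSE)
  .with_seed(seed, {
    lambda <- rep(background * bin_time, n_bins)
    truth <- list()
    for (sp in species) {
      alpha <- sp$alpha %||% 1
      tau_diff <- if (!is.null(sp$tau_diff)) sp$tau_diff
                  else omega1^2 / (4 * sp$d)
      n_particles <- rpois(1, sp$concentration * constants$avogadro *
                             v_box_l)
      if (n_particles > 1e5) {
        stop("simulation would require ", n_particles,
             " particles (> 1e5); reduce concentration or box size",
             call. = FALSE)
      }
      if (alpha == 1) {
        d_cm2 <- omega1^2 / (4 * tau_diff)
        step_sd <- sqrt(2 * d_cm2 * bin_time)
      } else {
        # msd(t) = 2 * gamma * t^alpha per axis, with gamma set so the
        # lateral msd crosses omega1^2/... at tau_diff as for alpha = 1
        gam <- omega1^2 / (4 * tau_diff^alpha)
        t_edges <- (0:n_bins) * bin_time
        step_sd <- sqrt(2 * gam * diff(t_edges^alpha))
      }
      if (n_particles > 0 && sp$brightness > 0) {
        lambda <- lambda + bd_expected_counts(
          n_bins, n_particles, as.numeric(step_sd),
          omega1, omega_z, half_x, half_x, half_z,
          sp$brightness * bin_time)
      }
      truth[[length(truth) + 1]] <- list(
        concentration = sp$concentration,
        n_in_veff = sp$concentration * constants$avogadro * v_eff,
        tau_diff = tau_diff, alpha = alpha,
        n_particles = n_particles)
    }
    counts <- rpois(n_bins, lambda)
    photon_trace(counts, bin_time,
                 meta = list(truth = truth, omega1 = omega1, s = s,
                             v_eff = v_eff))
  })
}

#' Simulate a two-channel ddPCR droplet well
#'
#' Per droplet, template copies of the reference (HEX) amplicon are
#' Poisson with mean `lambda_hex`; each copy independently retains the
#' break-spanning (FAM) amplicon with probability
#' 1 - `true_dsb_fraction` (a break destroys the FAM amplicon on that
#' template). Droplets with at least one intact copy of an amplicon
#' draw their amplitude from the positive cluster, the rest from the
#' negative cluster.
#'
#' @param n_droplets Droplet count; >= 1000.
#' @param lambda_hex Mean template copies per droplet.
#' @param true_dsb_fraction Fraction of loci carrying a break, [0, 1].
#' @param clusters Amplitude cluster parameters: list with `neg_mean`,
#'   `neg_sd`, `pos_mean`, `pos_sd` (defaults 1000/100/8000/300).
#' @param well_id,is_reference Passed to [droplet_well()].
#' @param seed Integer seed.
#' @return A [droplet_well()].
#' @export
simulate_droplets <- function(n_droplets = 20000L, lambda_hex = 0.3,
                              true_dsb_fraction = 0,
                              clusters = list(neg_mean = 1000,
                                              neg_sd = 100,
                                              pos_mean = 8000,
                                              pos_sd = 300),
                              well_id = "S01", is_reference = FALSE,
                              seed = NULL) {
  if (n_droplets < 1000) stop("n_droplets must be >= 1000", call. = FALSE)
  if (true_dsb_fraction < 0 || true_dsb_fraction > 1) {
    stop("true_dsb_fraction must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    hex_copies <- rpois(n_droplets, lambda_hex)
    fam_copies <- rbinom(n_droplets, hex_copies, 1 - true_dsb_fraction)
    amp <- function(positive) {
      ifelse(positive,
             rnorm(n_droplets, clusters$pos_mean, clusters$pos_sd),
             rnorm(n_droplets, clusters$neg_mean, clusters$neg_sd))
    }
    droplet_well(amp(hex_copies > 0), amp(fam_copies > 0),
                 well_id = well_id, is_reference = is_reference)
  })
}

#' Simulate a dose-response table
#'
#' Evaluates a 4PL curve at the given doses and adds seeded Gaussian
#' noise in percentage points, clamped to [0, 100].
#'
#' @param ec50 Half-maximal dose.
#' @param doses Dose levels (molecules/cell).
#' @param bottom,top,hill 4PL parameters; defaults 0, 80, 1.
#' @param noise_sd Noise SD in percentage points; default 3.
#' @param n_replicates Replicates per dose; default 1.
#' @param condition Label.
#' @param seed Integer seed.
#' @return Data frame with columns `dose_per_cell`, `response_pct`,
#'   `condition`, `replicate`.
#' @export
simulate_dose_response <- function(ec50, doses, bottom = 0, top = 80,
                                   hill = 1, noise_sd = 3,
                                   n_replicates = 1L,
                                   condition = "sim", seed = NULL) {
  stopifnot(ec50 > 0, all(doses >= 0))
  ld <- suppressWarnings(log10(doses))
  frac <- 1 / (1 + 10^(hill * (log10(ec50) - ld)))
  frac[doses == 0] <- 0
  mu <- bottom + (top - bottom) * frac
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      resp <- mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
      data.frame(dose_per_cell = doses,
                 response_pct = pmin(pmax(resp, 0), 100),
                 condition = condition, replicate = r,
                 stringsAsFactors = FALSE)
    }))
    out
  })
}

#' Simulate an editing time course
#'
#' Two-compartment linear kinetics: intact loci are cut at rate
#' `k_cut` (per hour) and cut loci resolve into indels at rate
#' `k_repair`. Closed forms:
#' uncut(t) = exp(-k_cut t);
#' dsb(t) = k_cut/(k_repair - k_cut) (exp(-k_cut t) - exp(-k_repair t));
#' indel(t) = 1 - uncut - dsb. Both observable courses are returned as
#' percent of `plateau` (the maximal editable fraction). In the fast-
#' repair limit the indel course is the saturating exponential
#' plateau * (1 - exp(-k_cut t)), so the half-max time is
#' log(2)/k_cut.
#'
#' @param k_cut,k_repair Rates per hour, > 0.
#' @param plateau Maximal editing in percent.
#' @param times Sampling times in hours.
#' @param noise_sd Optional Gaussian noise in percentage points.
#' @param seed Integer seed.
#' @return Data frame with `time_h`, `dsb_pct`, `indel_pct`.
#' @export
simulate_timecourse <- function(k_cut, k_repair, plateau = 80,
                                times = seq(0, 54, by = 2),
                                noise_sd = 0, seed = NULL) {
  stopifnot(k_cut > 0, k_repair > 0, all(times >= 0))
  uncut <- exp(-k_cut * times)
  dsb <- if (abs(k_repair - k_cut) < 1e-12 * k_cut) {
    k_cut * times * exp(-k_cut * times)
  } else {
    k_cut / (k_repair - k_cut) * (exp(-k_cut * times) -
                                    exp(-k_repair * times))
  }
  indel <- 1 - uncut - dsb
  .with_seed(seed, {
    noise <- function(x) {
      if (noise_sd > 0) x + rnorm(length(x), 0, noise_sd) else x
    }
    data.frame(
      time_h = times,
      dsb_pct = pmin(pmax(noise(plateau * dsb), 0), 100),
      indel_pct = pmin(pmax(noise(plateau * indel), 0), 100))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
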