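# shared ground-truth parameter sets for recovery tests

two_comp_truth <- function(n_molecules = 5) {
  list(model = "two_component", n_molecules = n_molecules,
       tau_diff1 = 1e-3, tau_diff2 = 5e-3, alpha = 0.8, f_fast = 0.6)
}

one_comp_truth <- function(n_molecules = 5, tau_diff = 2e-3) {
  list(model = "one_component", n_molecules = n_molecules,
       tau_diff = tau_diff)
}

# an intensity-modulated Poisson trace with a smooth, slowly decaying
# autocorrelation (OU-modulated rate), for correlator oracle checks
ou_poisson_trace <- function(n_bins = 4096, corr_bins = 200,
                             mean_rate = 20, mod_sd = 0.35, seed = 42,
                             bin_time = 1e-3) {
  set.seed(seed)
  phi <- exp(-1 / corr_bins)
  x <- numeric(n_bins)
  x[1] <- rnorm(1)
  innov <- rnorm(n_bins) * sqrt(1 - phi^2)
  for (i in 2:n_bins) x[i] <- phi * x[i - 1] + innov[i]
  lambda <- mean_rate * exp(mod_sd * x - mod_sd^2 / 2)
  photon_trace(rpois(n_bins, lambda), bin_time)
}
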