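# fcsquant

Absolute quantification of nuclear protein delivery by fluorescence
correlation spectroscopy (FCS), with the downstream dose–response and
droplet-digital-PCR (ddPCR) analyses needed to compare genome-editing
delivery modalities.

The question the package is built around: **how many Cas9
ribonucleoproteins (RNPs) actually reach a cell nucleus, and how does
that number relate to the delivered dose and to editing outcomes?**
FCS answers the first part — the autocorrelation
$G(\tau) = \frac{1}{N}\frac{1}{(1+\tau/\tau_d)\sqrt{1+s^2\tau/\tau_d}}$
of fluorescence fluctuations in a calibrated confocal volume has
amplitude $1/N$, and with $V_\mathrm{eff}$ known, $N$ becomes a molar
concentration ($C = N/(N_A V_\mathrm{eff})$) and a nuclear copy number
($N_\mathrm{nucleus} = C\,V_\mathrm{nuc}\,N_A$). Dose–response fits
(four-parameter logistic, EC50/EC90, fold-changes) and Poisson-corrected
ddPCR double-strand-break quantification
($\%\mathrm{DSB} = 100\,(1-[\mathrm{FAM}]/[\mathrm{HEX}])$) handle the
second part.

It is intended for quantitative microscopists and genome-editing
researchers who have (or simulate) autocorrelation curves, photon-count
traces, droplet amplitude tables, or dose/time-course tables, and want
a tested, scriptable alternative to instrument-vendor analysis chains.

## What's inside

| Stage | Functions |
|---|---|
| Autocorrelation models (1-component, anomalous, 2-component) | `acf_one_component()`, `acf_anomalous()`, `acf_two_component()` |
| Confocal volume calibration with temperature-corrected dye constants | `temp_correct_diffusion()`, `lateral_waist()`, `effective_volume()`, `calibrate_focal_volume()` |
| Correlators (direct reference + multi-tau, segment averaging) | `acf_direct()`, `acf_multitau()`, `acf_segment_average()` |
| Model fitting, selection, quality control | `fcs_fit()`, `select_model()`, `qc_filter()`, `condition_summary()` |
| Nuclear copy numbers | `concentration_from_n()`, `molecules_per_nucleus()`, `bound_concentration()`, `per_cell_fraction()`, `nuclear_quant()` |
| Dose–response and editing kinetics | `dose_response()`, `ec_at()`, `fold_change()`, `dose_conc_regression()`, `halfmax_time()`, `editing_rate()` |
| ddPCR DSB quantification | `droplet_thresholds()`, `quantify_droplets()`, `quantify_droplet_wells()` |
| Seeded simulators with known ground truth | `simulate_acf()`, `simulate_fcs_trace()`, `simulate_droplets()`, `simulate_dose_response()`, `simulate_timecourse()` |
| Delimited-text I/O | `read_acf()`/`write_acf()`, `read_photon_trace()`, `read_droplets()`, `read_dose_table()`, `read_timecourse()`, `fit_acf_files()` |

`fcs_fit()` and `dose_response()` return classed model objects with
`print`, `summary`, `coef`, `predict`, `residuals`, `plot`, and
`simulate` methods.

## Worked example

Calibrate the focal volume from simulated dye-standard curves, quantify
a simulated nuclear RNP condition, and compare delivery modalities:

```r
library(fcsquant)

## 1. effective volume from a dye standard (Alexa 594 at 37 C)
d37 <- temp_correct_diffusion(3.88e-6, 37)        # 5.20e-6 cm^2/s
tau_dye <- (2.04e-5)^2 / (4 * d37)
dye_curves <- simulate_acf(
  list(model = "one_component", n_molecules = 2, tau_diff = tau_dye),
  noise_sd = 0.02, n_curves = 10, seed = 1, lag_range = c(1e-6, 0.1))
cal <- calibrate_focal_volume(dye_curves, dye_standard("alexa_594"))
cal
#> Confocal effective volume calibration
#>   dye: alexa_594 at 37 C (D = 5.2e-06 cm^2/s), 10 traces
#>   structure factor s = 0.17 (fixed)
#>   mean tau_diff = 2e-05 s
#>   omega1 = 0.204 um; V_eff = 0.277 fl

## 2. fit + QC a nuclear RNP condition (truth: N = 5, F_fast = 0.6)
curves <- simulate_acf(
  list(model = "two_component", n_molecules = 5, tau_diff1 = 1e-3,
       tau_diff2 = 5e-3, alpha = 0.8, f_fast = 0.6),
  noise_sd = 0.02, n_curves = 25, seed = 2)
fits <- lapply(curves, function(cv) qc_filter(fcs_fit(cv)))
nuclear_summary(nuclear_quant(fits, cal, dose_per_cell = 7.2e6))
#>   condition n_cells mean_conc_nM sem_conc_nM mean_n_nucleus n_nucleus_2sf
#> 1       all      25     29.95718  0.02745306       12448.04         12000
#>   mean_c_bound_nM mean_nuclear_fraction
#> 1        12.45281           0.001728894

## 3. dose-requirement fold-change between modalities
round(fold_change(2.4e6, 5.7e4))   # electroporation vs EDV EC50s
#> [1] 42

## 4. ddPCR %DSB with thresholds from an untreated reference well
ref <- simulate_droplets(20000, lambda_hex = 0.5, true_dsb_fraction = 0,
                         seed = 3, is_reference = TRUE)
wel <- simulate_droplets(20000, lambda_hex = 0.5, true_dsb_fraction = 0.5,
                         seed = 4)
quantify_droplets(wel, droplet_thresholds(ref))
#> ddPCR well S01 (poisson mode): 20000 droplets
#>   HEX+ 7865 (lambda 0.5), FAM+ 4350 (lambda 0.245)
#>   %DSB = 50.9
```

Reading the numbers: the calibration recovers the 0.2 µm waist and a
0.28 fl effective volume (inside the plausible 0.25–0.4 fl range for a
high-NA confocal). The 25 simulated cells average ~30 nM nuclear RNP —
about 12 000 copies per nucleus at the 690 µm³ HeLa nuclear volume, of
which ~12 nM is chromatin-bound (the slow fraction) — and only ~0.2% of
the delivered dose in this configuration. The EC50 ratio says
electroporation needs ~42× more Cas9 than packaged delivery for the
same half-maximal editing, and the ddPCR well recovers the simulated
50% break fraction.

See the vignette (`vignettes/fcs-quantification.Rmd`) for the models,
their assumptions, and all numerical choices.

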