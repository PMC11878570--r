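---
title: "Quantifying nuclear Cas9 delivery with FCS, dose-response and ddPCR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear Cas9 delivery with FCS, dose-response and ddPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsquant)
```

## The measurement problem

Fluorescence correlation spectroscopy (FCS) measures the fluctuating
fluorescence of labeled molecules crossing a diffraction-limited
confocal volume. The normalized autocorrelation of that signal,
$G(\tau)$, carries two pieces of information: its zero-lag amplitude
is $1/N$, the inverse of the mean number of molecules in the effective
volume, and its decay time $\tau_{\mathrm{diff}}$ is the mean dwell
time of a molecule in the volume. With the effective volume
$V_{\mathrm{eff}}$ calibrated, $N$ converts to an absolute molar
concentration — which is what makes FCS suitable for asking how many
Cas9 ribonucleoproteins (RNPs) actually reach a cell nucleus under a
given delivery modality, and how that number relates to the delivered
dose and to editing outcomes.

This package implements that chain end to end: calibration, photon
correlation, model fitting with quality control, conversion to nuclear
copy numbers, dose-response analysis of editing efficiency, and
droplet-digital-PCR (ddPCR) quantification of double-strand breaks
(DSBs). Because raw microscope and droplet-reader exports are rarely
public, the package also ships seeded simulators for every input, with
known ground truth, so the full pipeline is testable end to end.

## Autocorrelation models

Three closed-form models are provided, all with the structure factor
$s$ (the radial/axial ratio of the Gaussian detection volume) held
fixed:

* **One component** (`acf_one_component()`), free 3D diffusion:
  $G(\tau) = \frac{1}{N}\,
  \frac{1}{(1+\tau/\tau_d)\sqrt{1+s^2\tau/\tau_d}}$.
  Used for dye standards and any single freely diffusing species.
* **Anomalous** (`acf_anomalous()`): $\tau/\tau_d$ is replaced by
  $(\tau/\tau_d)^\alpha$, with $\alpha<1$ describing subdiffusion in
  crowded or binding-hindered environments, plus an additive offset
  $G(\infty)$.
* **Two component** (`acf_two_component()`): an $F_{\mathrm{fast}}$
  weighted additive mixture of a fast free component
  ($\tau_{\mathrm{diff1}}$) and a slow anomalous component
  ($\tau_{\mathrm{diff2}}, \alpha$) — the appropriate description for
  a DNA-binding protein in a nucleus, where free and chromatin-bound
  populations coexist. The slow fraction $1-F_{\mathrm{fast}}$ is
  read as the DNA-bound population.

Two typographic variants found in the literature are implemented
behind options rather than silently chosen. First, the two-component
expression is sometimes typeset with the two bracketed terms
*multiplied*; that form makes the zero-lag amplitude
$F(1-F)/N$ instead of $1/N$, contradicting the meaning of $N$ as a
molecule count, so the additive mixture is the default and the product
form is retained as `form = "literal_product"` for fidelity checks
only. Second, the anomaly exponent is sometimes typeset on the whole
factors $(1+\tau/\tau_d)^\alpha$ rather than on the lag ratio inside
them; the conventional placement (`exponent = "standard"`, on the
ratio) is the default and the other is available as `"printed"`. The
two placements coincide at $\tau=\tau_d$ and at $\alpha=1$, and the
test suite exercises both.

The structure factor defaults to $s = 0.17$, a value measured once
with a dye standard and then held fixed in every fit; it is a
configured constant of the optical setup, never a free parameter.
Avogadro's number defaults to the CODATA value; analyses in this
domain sometimes print the older $6.023\times10^{23}$, a difference
below 0.02% and irrelevant at reporting precision.

## Calibrating the effective volume

`calibrate_focal_volume()` fits the one-component model to replicate
dye-standard curves, averages $\tau_{\mathrm{diff}}$, and applies

$$\omega_1 = \sqrt{4 D \tau_{\mathrm{diff}}}, \qquad
V_{\mathrm{eff}} = \pi^{3/2}\,\omega_1^3 / s .$$

Literature diffusion coefficients are tabulated at 25&deg;C while
live-cell work runs at 37&deg;C, so `temp_correct_diffusion()` applies
the Stokes-Einstein scaling
$D(t) = D(25) \cdot (t+273.15)/\eta(t) \cdot 2.985\times10^{-6}$
Pa&nbsp;s/K. The constant is chosen so the correction is exactly the
identity at 25&deg;C. The water viscosity curve is pinned at
$\eta(25) = 8.90\times10^{-4}$ and $\eta(37)=6.913\times10^{-4}$
Pa&nbsp;s and interpolated with an Arrhenius form
$\eta(T)=A e^{B/T}$ between and slightly beyond these points (valid
0&ndash;60&deg;C); only the two pinned temperatures matter for the
standard workflow. For Alexa Fluor 594
($D_{25} = 3.88\times10^{-6}$ cm^2^/s) this yields
$D_{37} = 5.20\times10^{-6}$ cm^2^/s:

```{r}
temp_correct_diffusion(3.88e-6, 37)
```

A calibration resulting in $V_{\mathrm{eff}}$ outside 0.25&ndash;0.4
fl — the plausible range for a high-NA confocal system — is flagged
with a warning rather than rejected, since the bound is a sanity
check, not a physical law.

## From photons to curves

`acf_direct()` implements the textbook $O(NK)$ estimator
$G(\tau_k) = \langle \delta F(t)\,\delta F(t+\tau_k)\rangle /
\langle F\rangle^2$ on a linear lag grid; it exists as the reference
that the production correlator is verified against.
`acf_multitau()` is a standard multi-tau scheme (16 lags per level,
factor-2 coarsening) covering many decades of lag at
$O(N \log N)$ cost. Its default *symmetric* normalization divides by
the means of the two shifted segments, which suppresses the bias a
slow intensity drift induces in the plain global-mean estimator; a
`"plain"` mode reproduces the direct estimator exactly on uncoarsened
lags. The two estimators differ by design on drifting signals, so the
oracle-equivalence tests compare like with like: matched
normalization, agreement to machine precision at native lags and to
well under 2% per shared lag after coarsening (assessed on a smooth
deterministic intensity, where the only difference left is the
coarsening itself). Lag zero is excluded from all curves — it is
dominated by shot noise, which is uncorrelated between bins.

`acf_segment_average()` mirrors the standard acquisition practice of
recording ten sub-traces per measurement: it splits a long trace into
`n_segments` (default 10) equal parts, correlates each, and returns
the per-lag mean with the standard error of the mean as `g_se`. These
SEs become the weights in fitting, which makes the reduced chi-square
interpretable.

## Fitting and quality control

`fcs_fit()` performs weighted Levenberg-Marquardt fitting (via
minpack.lm) with several numerical safeguards:

* Scale parameters ($N$, diffusion times) are fitted on the log
  scale; bounds are $N \in (10^{-3}, 10^4)$, times
  $\in (10^{-6}, 1)$ s, $\alpha \in (0.05, 1.5)$,
  $F_{\mathrm{fast}} \in [0, 1]$.
* The slow time is parameterized as
  $\tau_{\mathrm{diff2}} = \tau_{\mathrm{diff1}}(1+\delta)$ with
  $\delta > 0$, so the fast/slow labels cannot switch during
  optimization.
* Initialization is data-driven — amplitude from the first lag, the
  fast time from where the curve falls to half its first-decade
  plateau, $F_{\mathrm{fast}} = 0.5$ — plus three deterministically
  jittered restarts ($\tau$ scaled by 0.3 and 3, the fraction moved
  to 0.3 and 0.7). Fixed jitters rather than random ones keep every
  fit bit-reproducible without threading a seed through the fitting
  layer. The best converged start by chi-square wins.
* The chi-square is *reduced* by default (weighted SSR divided by
  $n_{\mathrm{lags}} - n_{\mathrm{params}}$), making the conventional
  rejection cutoff comparable across lag-grid sizes; a `"raw"` mode
  exists because published cutoffs do not always state their
  normalization, and the choice is recorded on the fit object.

`select_model()` compares one- versus two-component fits by
chi-square, with ties (within $10^{-9}$ relative) going to the
simpler model. `qc_filter()` then stamps the standard rejection rules
for nuclear RNP measurements, each configurable:
$\tau_{\mathrm{diff1}} < 0.5$ ms (signal dominated by free labeled
RNA), $\tau_{\mathrm{diff1}} > 10$ ms (aggregation),
$\alpha < 0.3$, $\chi^2 > 30$, and absence of a second component when
one was requested. All violated rules are reported, not just the
first, and the filter is a pure function of the recorded fit.
`condition_summary()` enforces the reporting convention that a
condition needs at least 20 accepted curves.

A fitted curve reports three diffusion-time summaries — the fast
time, the slow time, and the $F_{\mathrm{fast}}$-weighted mean — via
its coefficients, since published per-cell "diffusion times" do not
always state which of the three they quote; the per-cell tables carry
the full parameter set so any convention can be reproduced.

## From fits to nuclear copy numbers

For accepted fits, concentration and copy number follow from

$$C = \frac{N}{N_A V_{\mathrm{eff}}}, \qquad
N_{\mathrm{nucleus}} = C \cdot V_{\mathrm{nuc}} \cdot N_A,$$

with $V_{\mathrm{nuc}} = 6.90\times10^{-13}$ l (690 &mu;m^3^, the
published HeLa nuclear volume) as the default. At a nuclear
concentration of 3.2 nM this gives roughly 1300 molecules per
nucleus:

```{r}
molecules_per_nucleus(3.2e-9)
```

Copy numbers are reported to two significant figures in summaries
(16&nbsp;000, 1200, ...), with full precision retained in the data
frames.

The DNA-bound concentration defaults to the complement form
$C_{\mathrm{bound}} = (1-F_{\mathrm{fast}})\,C$, because in the
two-component model the bound population *is* the slow fraction. The
literal form $C/F_{\mathrm{fast}}$, which appears in print, is also
implemented (`mode = "literal"`); it exceeds the total concentration
whenever $F_{\mathrm{fast}} < 1$, which is physically impossible for
a sub-population, so its output is flagged with a warning rather than
silently corrected. Neither form is altered; the choice is explicit.

## Dose-response and kinetics

`dose_response()` fits the four-parameter logistic
$r(x) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/
(1+(\mathrm{EC50}/x)^{h})$ on log10 dose, with bottom $\ge 0$ and top
$\le 100$ because responses are percentages. `ec_at()` inverts the
fit in closed form (EC90 $= 9\times$EC50 at $h = 1$), `fold_change()`
forms dose-requirement ratios between delivery modalities, and
`dose_conc_regression()` provides the linear dose-to-nuclear-
concentration calibration with an extrapolation warning beyond twice
the fitted range.

For editing time courses, `halfmax_time()` defines half-max relative
to the fitted plateau, not to 100%. The plateau is taken from the
saturated tail of the course when the final fifth is demonstrably
flat (spread below 5% of the maximum), and from a 4PL fitted in time
otherwise; the crossing time is then read from the measured course by
linear interpolation. Reading the crossing from the data rather than
from the sigmoid keeps the estimate accurate when the kinetics are
saturating-exponential (for which a logistic's midpoint is biased
late by several percent). `editing_rate()` is the windowed
finite-difference slope with interpolated endpoints.

`simulate_timecourse()` generates ground truth for these estimators
from two-compartment linear kinetics (intact &rarr; cut &rarr;
repaired), chosen as the simplest mechanism that reproduces the
observed shape — a transient DSB peak resolving into a saturating
indel curve; no published kinetic model exists for these experiments,
so the generator is a package design choice, not a reimplementation.

## ddPCR quantification of double-strand breaks

The DSB assay places a reference amplicon (HEX probe) next to the cut
site and a second amplicon (FAM probe) across it; an unrepaired break
or a lost chromosome destroys the FAM template. The statistic is

$$\%\mathrm{DSB} = 100 \times \left(1 -
\frac{[\mathrm{FAM}]}{[\mathrm{HEX}]}\right),$$

with channel concentrations in copies per droplet. By default these
are Poisson-corrected, $\lambda = -\ln(1 - p_+)$, because droplet
readers report concentrations, and the raw positive fraction
understates the copy number once droplets carry multiple templates.
The `raw_counts` mode exposes exactly that bias for sensitivity
analysis (at $\lambda = 1$ it is tens of percent; the tests assert
it). Negative values arising from noise are clamped to zero with a
warning, never silently.

`droplet_thresholds()` reproduces the practice of thresholding
against untreated wells: two-means clustering per channel, threshold
midway between the negative cluster's upper edge (mean + $k$SD,
$k = 5$) and the positive cluster's lower edge, with a mean + $k$SD
fallback and warning when a channel is unimodal.

## The simulators, and what passing tests do and do not show

`simulate_acf()` is the fast path: exact model curves plus
multiplicative Gaussian noise whose relative SD grows linearly in
log-lag from 1&times; to 3&times; the nominal level, mimicking the
variance profile of a real correlator; the true per-lag SD is
attached as `g_se`, so weighted fits of simulated data have reduced
chi-square near 1.

`simulate_fcs_trace()` is the physical path: Brownian dynamics of
point emitters in a periodic box with a 3D Gaussian detection
profile and per-bin Poisson photon counts. Particle numbers are
Poisson-drawn per trace so amplitude statistics are realistic.
Anomalous motion uses variance-rescaled Gaussian increments (1D MSD
$= 2\Gamma t^\alpha$) rather than true fractional Brownian motion —
adequate here because the fitting target is the ACF shape, and
documented as an approximation. The box half-width is 3 lateral
waists in $x$/$y$ and 3 axial waists in $z$: the detection profile at
3$\omega_1$ laterally is below $10^{-7}$ of its peak, so a wider
lateral box (e.g. 3 axial waists in every axis, which with
$s = 0.17$ is ~18$\omega_1$) would add a ~35-fold excess of particles
that never produce photons. Positions advance one step per bin, so
the bin time must be well below $\tau_{\mathrm{diff}}$ (the tests use
$\tau_{\mathrm{diff}}/20$).

What the simulators deliberately omit: detector afterpulsing and
dead-time, triplet blinking, optical aberrations, cell-to-cell
variation in nuclear volume, autofluorescence background structure,
and rain (intermediate droplets) in ddPCR. Passing recovery tests
therefore demonstrates that the *analysis* is correct and unbiased
under the stated noise models — not that these instrument and
biology effects are negligible in real data. The quantities that
depend on real measurements (per-cell diffusion times, measured
nuclear concentrations, half-max editing times for specific doses)
cannot be reproduced without the raw data; the tests instead verify
the machinery that produced them at matched problem sizes.

## Problem sizes and numerical choices

The test and reproduction-script workloads were sized to what a desk check
needs, not what an instrument produces: 50 simulated curves per
condition at $N \in \{2, 5, 20\}$ (2% noise) for parameter recovery;
a single 60 s, $5\times10^{-5}$ s-bin Brownian-dynamics trace at
$\langle N\rangle = 5$ for the end-to-end path; 20&nbsp;000 droplets
per simulated well at occupancies 0.2 and 1.0; 100 replicate dose
tables at 3% noise for the EC50 bias study. Degenerate inputs error
early and informatively: non-positive lags, unordered diffusion
times, fractions outside [0,1], saturated droplet channels, windows
outside the measured range, curves with fewer than 20 lags or under
3 decades of lag span.

## Known limitations

* The anomalous-motion generator approximates fBm; its fitted
  $\alpha$ recovers the generator's exponent through the ACF shape
  but subtle increment-correlation effects are not modeled.
* No triplet/photophysics term exists in the models, so real curves
  with strong microsecond blinking need their short lags trimmed
  before fitting.
* Confidence intervals on FCS parameters are not computed
  analytically; use `simulate()` on a fit for a parametric-bootstrap
  view.
* The dose-to-concentration regression is deliberately linear (that
  is the observed behavior over the dose range it is used for) and
  warns rather than refuses on extrapolation.
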