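---
title: "Models and methods behind trxps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trxps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxps)
```

# The experiment this package models

trxps analyses pump-probe, time-resolved X-ray photoelectron spectroscopy
(TR-XPS) of photoexcited molecules, built around the UV-induced relaxation
of gas-phase uracil probed at the oxygen and nitrogen K-edges. A 264 nm
(4.70 eV) pump promotes ~9% of the molecules to the bright S2(pi pi\*)
state; a soft X-ray probe ionizes O 1s / N 1s core levels at a variable
delay. UV-on and UV-off spectra are recorded in consecutive shots, so each
dataset is a pair of two-dimensional maps (binding energy x delay). The
package provides every step between those maps and the published
observables: transient spectrum synthesis from tabulated stick spectra,
closed-form branching population kinetics, difference maps and scaled
subtraction, region-integrated time traces, a shared-parameter global
kinetic fit, hot-ground-state peak tracking, and Fourier analysis of
coherent intensity oscillations - plus a synthetic-data generator that
emulates the experiment so every estimator is validated by parameter
recovery.

# Kinetic model

The relaxation scheme is a branching cascade driven by a Gaussian
excitation pulse (the pump-probe cross-correlation):

* a fraction `phi_hgs` (default 0.36, the theoretical branching ratio; the
  experimental literature value 45% can be configured) returns
  *instantaneously* to a vibrationally hot ground state (HGS), because the
  intermediate residence time is below the instrument response;
* the rest populates S2(pi pi\*), which undergoes internal conversion to
  S1(n pi\*) with time constant `tau_ic` (17 fs at the study conditions);
* S1 crosses to the triplet manifold with `tau_isc` (1.6 ps). There is no
  S1 -> S0 channel: the ground-state depletion never recovers.

Under a Gaussian source every population has a closed form built from the
exponentially modified Gaussian (EMG),

$$h(t) = \tfrac12\, e^{\sigma^2/2\tau^2 - (t-t_0)/\tau}\,
  \mathrm{erfc}\!\left(\frac{\sigma/\tau - (t-t_0)/\sigma}{\sqrt 2}\right),$$

evaluated through the scaled complementary error function so that extreme
`sigma/tau` ratios and nanosecond delays do not overflow (an asymptotic
expansion takes over where `erfcx` itself would). The sequential S1 filling
uses the standard two-step form with an analytic branch for the degenerate
case `tau_ic == tau_isc` (obtained by differentiating the EMG with respect
to the rate), not a numerical perturbation. The closed forms are tested
against a fourth-order ODE integration of the same scheme at 0.1 fs
resolution (agreement better than 1e-6 in absolute population).

Widths are stored internally as Gaussian sigma. Quoted cross-correlation
numbers (80.5 fs) are treated as fwhm: the quadrature sum of the 75 fs pump
and ~30 fs probe durations (~80.8 fs) is only consistent with the fwhm
reading. Every fit report records this convention.

# Spectral model

The packaged tables hold the theoretical O 1s and N 1s ionization energies
of the ground, S1(n pi\*) and S2(pi pi\*) states (RASPT2/aug-cc-pVDZ at the
Franck-Condon geometry), transcribed verbatim. Pole strengths are not
published; the default is 1.0 per line (0.1 for the weak S2 shake-down
satellite near 534 eV), configurable. Theory energies are rigidly shifted
(-2.4 eV O 1s, -2.1 eV N 1s) onto the experimental scale. Triplet energies
are not tabulated either; two synthetic default lines represent the
transient band observed at 539-542 eV and are clearly labelled as package
defaults. Relative strengths of the S1 doublet components are likewise an
assumption (equal), flagged here.

Lines are broadened with unit-area profiles - Lorentzian 0.4 eV fwhm for
theory-style spectra, or a Gaussian instrumental profile (0.8 eV fwhm O 1s,
1.0 eV N 1s, the package's one-time choice of a realistic monochromatized
magnetic-bottle resolution) for the synthetic maps. Broadening is linear
and area-conserving (checked by grid-refinement).

**Depletion bookkeeping.** In `composite_spectrum()` and the generator,
every excited state's total strength is renormalized to the ground-state
total, and the UV-on map is
$(1 - fC(t))\,\mathrm{GS} + \sum_s p_s(t)\,S_s + p_\mathrm{hgs}(t)\,\mathrm{HGS}$,
so the integral of the negative (depletion) signal exactly balances the
integral of the excited-state signal at every delay. The site-resolved
physics - only the O8 binding energy shifts substantially while O7 is a
spectator - emerges naturally: the S1/S2 tables retain near-GS O7 lines
that refill the O7 part of the depletion, leaving the net negative feature
at the O8 position.

The HGS appears as a skew-normal line: location drifting linearly to +0.3 eV
(saturating at 1 ps), scale fixed at 1.6 eV fwhm, shape parameter 0.3
(mildly skewed toward high binding energy, where `asymmetry >= 0` implies
mean >= mode). The drift magnitude and saturation time are package choices
consistent with the observed upward drift of the main-line mean; the exact
time dependence of the published HGS simulation is not available.

# Synthetic data generator

`generate_map_pair()` produces UV-on/UV-off pairs with the full statistical
structure the analysis assumes:

* populations from the closed-form kinetics on the acquisition schedule
  (dense -200..+500 fs scan, default 20 fs steps, plus fixed delays at 1,
  10, 100 and 1000 ps);
* pump-probe sidebands: replicas of the ground-state spectrum displaced by
  +/- 4.70 eV, gated by the cross-correlation Gaussian, with amplitude
  `ratio x f` per sideband (`ratio` 0.23 for O 1s, 1.3 for N 1s). The
  replica intensity is borrowed from the main line, so total counts are
  conserved and the N 1s depletion shows the published transient
  "recovery" once the sideband channel closes;
* coherent nuclear motion: each coordinate carries a step extension of
  0.1 A at time zero with a damped cosine (modes at 114.6, 198.1 and
  292.7 cm^-1). Line positions shift linearly with the bond-length
  deviation (cross sections held constant). The C5C6 mode (292.7 cm^-1)
  moves the main S1 line across the D/E region boundary, producing the
  antiphase D/E intensity oscillations; the C4O8 mode (198.1 cm^-1) is
  coupled to the triplet line inside region D; an effective ring coordinate
  carries the 114.6 cm^-1 mode that oscillates the HGS line centre
  (antiphase A/C behaviour). The "ring" label extends the two bond labels
  because the low-frequency mode modulates the hot ground state rather than
  a specific excited-state line;
* independent Poisson counts per (binding energy, delay) pixel, scaled so
  `counts_scale` (default 1e4) is the expected count in the ground-state
  peak pixel per delay bin; a fixed seed gives bit-identical maps.

The S2 spectral drift from region A toward B over ~25 fs seen in the
published simulations is implemented (`s2_drift_eV`, `s2_drift_fs`) but
disabled in the `o1s_paper` preset: the experimental region-A decay is what
defines the 17 fs constant under the drift-free kinetic model, and enabling
the drift would make the generator structurally inconsistent with the model
being fitted - the preset emulates the experiment, not the simulation.

What the generator does *not* emulate: SASE photon-energy jitter,
space-charge shifts, detector nonlinearity, shot-to-shot intensity
correlations, two-photon UV ionization, and triplet-triplet conversion on
the 10-1000 ps scale. Passing recovery tests therefore demonstrate
estimator correctness under the stated statistical model, not robustness to
every systematic present in facility data.

# Reduction and estimators

`difference_map()` forms on - off with Poisson errors in quadrature.
`integrate_regions()` sums half-open binding-energy intervals `[lo, hi)`
(half-open to avoid double counting at shared printed boundaries); the
default O 1s set is the published A-F plus a sideband window at
531.5-533.5 eV centred on the printed 532.9 eV feature.

**Excited fraction.** `estimate_excited_fraction()` minimizes the squared
residual of `on - (1 - f) off` over a ground-state window and a late-delay
window (default 200-450 fs), subject to non-negativity of the delay-averaged
subtracted spectrum (with a 2-sigma Poisson allowance, applied only to
pixels carrying real signal - the max statistic over empty tail pixels is
fat-tailed). For uracil O 1s this plain estimator is intrinsically biased:
the S1 spectrum retains an O7 line ~0.1 eV from the ground-state doublet
and the HGS sits beneath the main peak, so part of the depletion is
refilled by excited-state intensity no window can exclude. The pipeline
therefore uses a model-based variant that adds non-negative contaminant
components (S1, S2, triplet, HGS shapes from the package's own spectral
model) to the regression; with those shapes the noiseless bias vanishes and
the recovered median over noisy replicates is within a few parts in a
thousand of the true value. The published analysis used a supporting-
information procedure that is not reproduced in the main text; the
model-based regression is this package's definition, and the method is
recorded in the output.

**Global fit.** All region traces are fitted simultaneously with four
shared nonlinear parameters (t0, IRF sigma, tau_ic, tau_isc) and
per-region non-negative component amplitudes plus a free baseline. The
amplitudes are solved by non-negative linear least squares inside the
nonlinear search (variable projection with the unconstrained baseline
projected out first); this keeps the sub-IRF tau_ic regime well
conditioned. Default component mapping: SB -> cross-correlation Gaussian;
A -> S2 + HGS step; C, D -> S1 + triplet; E -> S1 + sideband (the
high-energy sideband overlaps region E); F -> S1. Time constants are
searched in log space with bounds tau_ic in [1, 500] fs and tau_isc in
[0.1, 100] ps; t0 and sigma are initialized from a Gaussian pre-fit of the
sideband trace. Uncertainties come from the curvature of the weighted
least-squares objective, with a residual-resampling bootstrap
(`bootstrap_uncertainty()`) as the heavier alternative. The optimizer,
weighting (1/sigma^2) and error method are package choices, recorded in the
fit object.

An identifiability property worth knowing: with tau_ic far below the IRF
width, region E alone (the S1 rise) leaves tau_ic nearly unconstrained -
only the region-A S2 decay sharpens its profile. The test suite asserts
this as a chi-square profile comparison.

**Peak tracking.** `track_gs_peak()` fits a Gaussian plus linear baseline
per delay bin inside 536-539.4 eV, and reports separately the maximum
position of the map smoothed with Gaussian filters (18 fs along delay,
0.2 eV along energy). `windowed_spectra()` averages 108 fs windows and
smooths with sigma = 0.15 eV, reporting maxima. Non-convergent bins are
flagged, never fatal.

# Oscillation analysis

Residuals (trace minus fitted kinetic model) are mean-centred, resampled
onto the nominal 18 fs grid, Hann-apodized, zero-padded 8-fold and Fourier
transformed; the frequency axis is converted to cm^-1. Long delays
(>= 1 ps) are excluded (non-uniform sampling), the analysis band is
50-900 cm^-1 (below 50 cm^-1 is detrending-artifact territory), and the
peak floor is eight times the in-band median amplitude (Rayleigh-distributed
noise amplitudes stay below ~5x their median at this record length, while
genuine coherent peaks sit an order of magnitude above). The ~650 fs record
gives ~51 cm^-1 raw resolution; padding localizes peak positions on a
~6 cm^-1 grid but cannot resolve two modes inside one region - each
asserted region therefore carries a single dominant mode by generator
design. The published distinction between 114.6 and 114.8 cm^-1 is beyond
this record's true resolution and is reported, never asserted.

A known limitation: region A's 114.6 cm^-1 oscillation rides on the strong
S2 transient and the HGS drift and contributes only ~1.5 usable cycles, so
its top frequency is not localizable to the padded-bin level; the preset's
configured oscillation assignment covers regions C, D and E, where
single-mode recovery is robust. `lag_correlation()` reports the normalized
cross-correlation between intensity residuals and bond-length series over a
lag grid (antiphase relationships appear as negative coefficients at zero
lag), recovering constructed shifts such as the 30 fs offset used when
comparing calculated bond lengths with measured traces.

# Numerical and interface choices

* Delays in fs (positive = X-ray after UV), binding energies in eV
  everywhere; no other units cross an interface.
* Maps interchange as long-format TSV (`delay_fs`, `be_eV`, `counts_on`,
  `counts_off`) with the full generator truth record embedded as a JSON
  header comment; write-then-read is exact. Configurations serialize as
  YAML; unknown keys are rejected by name.
* `validate_config()` completes partial configurations from
  `default_config()`; unnamed list fields (modes, couplings) are replaced
  wholesale rather than merged.
* Reproducibility: every generator call is seeded; presets carry fixed
  seeds and regenerate identical maps; pipeline outputs embed the
  configuration hash and seed.
* Problem sizes: the synthetic maps use a 0.02 eV grid over 528-550 eV and
  a 40-point delay schedule; the recovery experiment behind the headline
  numbers uses 25 independent seeds at `counts_scale = 1e4`, which makes the
  per-seed depletion detectable at far more than 10 sigma per bin. These
  sizes were chosen once as representative of the experiment's statistics.

# Worked example

```{r example, eval = FALSE}
cfg <- preset("o1s_paper")
out <- run_pipeline(cfg)
tidy(out$fit)       # t0, sigma_irf, tau_ic, tau_isc, cc_fwhm
out$f               # excited-fraction estimate
oscillation_peaks(out$oscillations$E)

rec <- recovery_experiment("o1s_paper", seeds = 1:25)
summary(rec[c("tau_ic", "tau_isc", "sb_fwhm", "f")])
```

Every number quoted in the package documentation is produced by these code
paths; the test suite and `scripts/acceptance.R` recompute them from
scratch.
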