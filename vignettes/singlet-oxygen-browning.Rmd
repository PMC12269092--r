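---
title: "From browning trends to singlet-oxygen exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From browning trends to singlet-oxygen exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakephoto)
library(dplyr)
```

`lakephoto` chains four analyses that together connect long-term lake
browning — the rise of dissolved organic carbon (DOC) and water colour —
to the photochemical production of singlet oxygen (^1^O~2~) in lake
surface waters: trend classification, driver synchrony, quantum-yield
derivation, and a depth-averaged steady-state light-field model with a
contaminant screening step on top. This vignette explains each model,
its assumptions and tunable parameters, the design decisions taken where
the method was genuinely open, and what the synthetic-data generator
does and does not emulate.

## The steady-state singlet-oxygen model

The core quantity is the daily-average steady-state ^1^O~2~
concentration in the euphotic zone of a lake:

$$
[{}^1\mathrm{O}_2]_{ss}^{\,\mathrm{euph}}
 = \frac{\Phi_{app}}{k_d^{\Delta}} \times CF \times
   \sum_{\lambda=290}^{550}
   \frac{Z_{\lambda}}{z_{\mathrm{euph}}}
   \left(1 - e^{-K_{d,\lambda} z_{\mathrm{euph}}}\right)
   (1 - f_{\mathrm{backscatter}})\, f_{\mathrm{abs,CDOM}}
$$

where $\Phi_{app}$ (mol mol-photons^-1^) is the apparent quantum yield
of ^1^O~2~, $k_d^{\Delta}$ (s^-1^) the pseudo-first-order deactivation
rate constant of ^1^O~2~ by water, $CF$ a non-clear-sky correction
factor, $Z_\lambda$ the daily-average spectral photon irradiance
(mol-photons cm^-2^ s^-1^ nm^-1^, corrected for surface reflection and
in-water path-length amplification), $z_{\mathrm{euph}}$ the euphotic
depth (cm) and $K_{d,\lambda}$ the diffuse attenuation coefficient
(cm^-1^). The bracketed factor divided by depth is the depth-averaged
volumetric light absorption rate; `steady_state_1o2()` evaluates it by
trapezoidal integration on a 1 nm grid from 290 to 550 nm, and also
reports the **near-surface** variant in which
$(1 - e^{-K z})/z$ is replaced by its $z \to 0$ limit $K_{d,\lambda}$.
An epilimnion variant (same formula, user-supplied depth) is computed
only when a depth is passed, and is excluded from default pipeline
reports because an epilimnion depth is extra information the optical
sub-model cannot supply itself.

Both optical sub-models are driven by DOC alone:

* euphotic depth: $z_{\mathrm{euph}} = 4.6 / (0.15\,[\mathrm{DOC}]^{1.08}) \times 100$ cm;
* attenuation: $K_{d,\lambda} = \exp(-0.01347\,\lambda + 5.36\,[\mathrm{DOC}]^{0.157})$.

**A units decision.** The attenuation formula is conventionally printed
with cm^-1^ units, but taken literally at DOC = 4 mg C/L and
λ = 300 nm it gives ≈ 13.8 — as cm^-1^ this confines UV to millimetres
of water, flatly contradicting the ~7 m euphotic depths that the DOC
relationship above produces for the same lake. We therefore read the
formula's output in m^-1^ and convert to cm^-1^ (`kd_lambda()`,
argument `formula_units`, default `"m"`); the alternative reading
remains available as a toggle. With this reading, the mean ratio of
depth-averaged to near-surface concentration across a DOC 2–10 mg C/L
lake set is about 6 %, i.e. depth averaging costs roughly one order of
magnitude — consistent with light attenuation being the controlling
factor.

Default scalar constants (all arguments of `photo_constants()` and
`light_field()`, with units):

| constant | default | meaning |
|---|---|---|
| `k_rxn_ffa` | 1.0×10^8^ M^-1^s^-1^ | FFA + ^1^O~2~ rate constant, 25 °C |
| `k_d_delta` | 2.76×10^5^ s^-1^ | ^1^O~2~ deactivation by water (≈3.6 µs lifetime) |
| `phi_pna_slope`, `phi_pna_intercept` | 0.29 M^-1^, 0.00029 | PNA/pyridine actinometer quantum yield vs [pyridine] |
| `cf` | 0.60 | non-clear-sky correction |
| `f_backscatter` | 0.02 | light backscattered out of the column |
| `f_abs_cdom` | 1.0 | fraction of absorption attributable to CDOM |
| `surface_reflection` | 0.066 | air–water reflection loss |
| `pathlength_factor` | 1.2 | diffuse path-length amplification |

These are literature-typical values, not measured ones; every analysis
accepts overrides, and conclusions that depend on their exact values
(absolute concentrations, but not ratios or orderings) should be read
accordingly.

## Quantum yields from probe kinetics

A furfuryl alcohol (FFA) probe decays pseudo-first-order under
irradiation; `fit_first_order()` fits ln-concentration against time by
ordinary least squares. The in-vial steady state is
$[{}^1\mathrm{O}_2]_{ss} = k_{obs}/k_{rxn,FFA}$ and the apparent
quantum yield is $\Phi_{app} = [{}^1\mathrm{O}_2]_{ss}\,
k_d^{\Delta} / R_a$, with $R_a$ the in-vial rate of light absorption
computed from the sample absorbance spectrum and the (calibrated)
lamp spectrum (`rate_light_absorption()`). Lamp intensity is calibrated
with a *p*-nitroanisole (PNA)/pyridine actinometer:
$\Phi_{PNA} = 0.29\,[\mathrm{pyridine}] + 0.00029$, and the recovered
scale is the ratio of the observed PNA decay rate to the rate the
reference spectrum would produce (`actinometry_scale()`). The PNA molar
absorptivity curve used by both the generator and the inversion is a
synthetic single Gaussian band (peak 314 nm, ε~max~ 10^4^
M^-1^cm^-1^); the calibration round-trip depends only on the two sides
using the same curve, not on its exact literature shape. Yields can be
normalised against a Suwannee River NOM reference measured in parallel
(`phi_srnom` argument), the standard way to compare photoreactivity
across studies.

The synthetic kinetics generator (`gen_kinetics()`) inverts exactly this
math and adds multiplicative lognormal noise. Its default design is a
six-hour irradiation sampled half-hourly: at typical lake-water yields
(Φ ≈ 0.02) this decays the probe by one to two half-lives, which is
what real FFA experiments aim for and what makes the rate estimate
well-conditioned — with only ~40 % decay the 5 %-recovery property the
tests demand would fail for purely numerical reasons.

## Trend testing and browning classification

`seasonal_mann_kendall()` implements the seasonal Mann–Kendall test:
the S statistic sums pairwise value signs *within* calendar months
across years (so the annual cycle cannot masquerade as trend), the
variance uses the standard per-season tie correction, Z carries a ±1
continuity correction, and Sen's slope is the median of all
within-season pairwise slopes (per month, ×12 to per year). Slopes with
p ≥ 0.05 are carried as zeros into the classification stage — the
zero-replacement rule of the browning protocol. Missing months are
simply absent from their season's pair set; no imputation.

Two caveats are deliberate. First, the variance formula assumes serial
independence of observations within a season; with the AR(1) noise the
generator plants (φ = 0.5 at monthly lag; ≈ 0.5^12^ within a season,
but substantial *between* seasons) the test's empirical size at
α = 0.05 inflates to roughly 0.2 rather than 0.05. The test suite
asserts nominal size only on serially independent seasonal noise and
bounds the AR(1) case loosely; covariance-corrected variants are out of
scope. Second, Sen slopes for ties in time are undefined and such pairs
are skipped (they cannot arise at monthly resolution).

`classify_browning()` z-scores the zero-replaced DOC, colour and
SUVA~254~ slopes across lakes and runs k-means with k = 3 and 100
restarts under a fixed seed (rows are sorted by lake id first, so input
order cannot affect the result). Cluster labels are mapped
deterministically to the mild/moderate/intense ordering: A is the
cluster with the lowest mean standardized DOC + colour slope; of the
remaining two, C has the more negative mean standardized SUVA~254~
slope. If all lakes have identical slopes the classification is
degenerate and everything is assigned A with a warning.

## Wavelet coherence and phase classes

Series are prepared by `preprocess_series()`: shift to positive support
if needed, Box-Cox transform at the maximum-likelihood λ (profile
log-likelihood optimised over [-2, 3]), linear detrend, z-score. Gaps
up to 10 % are linearly interpolated and flagged; more is refused.

`cwt_morlet()` is an FFT-based continuous Morlet transform (ω₀ = 6,
zero padding to the next power of two, 24 scales per octave,
Torrence–Compo e-folding cone of influence). `wavelet_coherence()`
computes, at every time–scale pixel outside the cone, the unit-modulus
normalized cross product $w_x \overline{w_y}/(|w_x||w_y|)$ and averages
it over time, sites and the scales of a band; the modulus of that
average is the magnitude (0–1 by construction) and its argument the
mean phase. The standard bands are 3–6, 12–24 and 36–72 months. Note
the long band needs records of roughly 200+ months before any pixels
survive the cone of influence — with shorter records, restrict to the
short and intermediate bands.

**Phase convention.** phase = Arg(w~x~·conj(w~y~)), so a *positive*
phase means x (the response, DOC in the pipeline) leads y. A
quarter-cycle delay of y behind x at the 12-month scale gives +π/2; the
tests pin this. Phase classes follow the fixed intervals: positive
in-phase [-π/4, π/4], lagged positive (-3π/4, -π/4), lagged negative
(π/4, 3π/4), negative antiphase beyond ±3π/4, with boundaries assigned
to the in-phase/antiphase side.

Band significance uses phase-randomized Fourier surrogates of the y
series — the same random rotation applied at every site, preserving
each site's autocorrelation and the cross-site alignment of the
surrogate field — with the permutation-style estimate
p = (1 + #{surrogate ≥ observed})/(n + 1). The per-pixel normalization
here is one of several coherence definitions in use; equivalence with
any particular package's smoothing-based estimator is not claimed, and
what the tests pin is the qualitative behaviour: exactness at perfect
coherence and anticoherence, the planted-phase recovery, and nominal
rejection rates on independent noise.

## Contaminant screening

`half_life()` converts a bimolecular rate constant and a steady-state
concentration to t~1/2~ = ln 2/(k·c), in months of 30.44 days.
`screen_compounds()` compares that to the lake's hydraulic residence
time τ: log₁₀(t~1/2~/τ) below 0 means the ^1^O~2~ reaction outpaces
flushing, 0–1 comparable, above 1 slower (boundaries fall to the slower
class). As an anchoring point, the median contaminant rate constant
1.8×10^6^ M^-1^s^-1^ at the low end of euphotic-zone concentrations
(3.6×10^-16^ M) gives ≈ 407 months.

## What the synthetic data do and do not emulate

`gen_lakes()` / `gen_chemistry()` / `gen_drivers()` / `gen_kinetics()` /
`gen_spectrum()` / `gen_compounds()` / `gen_solar_spectrum()` generate
every input the pipeline consumes, seeded and byte-reproducible, with
the statistical structure the analysis assumes:

* monthly chemistry = linear trend + one annual harmonic + AR(1)
  noise (φ = 0.5, stationary sd 0.2 mg C/L by default), floored at
  small positive values; colour tracks DOC at ≈ 0.095 mg C/L per Pt–Co
  unit; colour records can end early and SUVA~254~ start late; an
  optional 5 % missing-at-random mask exercises gap handling;
* drivers are built from the Fourier band-limited component of DOC,
  phase-rotated by the requested offset and mixed with independent
  noise, so a planted (band, magnitude, phase) is recovered by the
  coherence stage — exactly at magnitudes 1 and 0, approximately in
  between;
* the clear-sky-like solar spectrum is a monotone spline through anchor
  points matching published mid-latitude daily-average photon spectra
  (sharp UV-B cutoff, 550 nm ≈ 5× the 330 nm flux), scaled to
  2×10^-9^ mol-photons cm^-2^ s^-1^ nm^-1^ at 550 nm;
* drainage lakes dominate the class mix (seepage rare), and seepage
  lakes carry high dissolved iron with low quantum yields, mirroring
  the iron-quenching contrast.

What is *not* emulated: real lake geography or any attempt to
reproduce specific monitored lakes; watershed or spatial processes;
fluorescence spectra (FI, HIX, β:α are pass-through scalars);
radiative-transfer modelling (spectra are consumed as tables);
epilimnion depths. Passing tests therefore demonstrate that the
analysis chain recovers known structure under its own assumptions —
linear trends, one seasonal harmonic, AR(1) noise, band-limited
coupling — not that it is robust to the full messiness of monitoring
data (changepoints, irregular sampling, heteroscedasticity, non-AR
persistence).

Where no value was stated for a generator default (noise levels,
variance, autocorrelation), one realistic value was chosen and kept;
these are placeholders for test power, not estimates of real-lake
parameters.

## Problem sizes and numerics

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as representative rather than exhaustive: 37-lake sets,
120–360-month records, 50–200 Monte-Carlo seeds, 99–999 surrogates per
coherence test. Numerical choices worth knowing: trapezoidal
integration on the 1 nm wavelength grid; Box-Cox λ by `optimize()` to
1e-6; k-means with 100 restarts; exact Mann–Whitney p-values for group
sizes ≤ 8 without ties and the tie-corrected normal approximation
otherwise; no multiple-testing correction on pairwise comparisons
(faithful to the figure-caption protocol, not a statistical
recommendation); constant series are a degenerate trend result (S = 0,
p = 1), not an error.

## Known limitations

* Absolute ^1^O~2~ concentrations inherit every light-field constant;
  treat them as order-of-magnitude estimates and prefer ratios and
  orderings across lakes.
* The seasonal Mann–Kendall size inflation under serial dependence is
  documented but uncorrected.
* The coherence magnitude for partially coupled series depends on the
  per-pixel normalization; planted intermediate magnitudes are
  recovered approximately, not exactly.
* Wavelet linear modelling (apportioning synchrony among drivers) and
  generalized additive modelling of quantum-yield predictors are out of
  scope.
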