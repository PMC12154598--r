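---
title: "Models and methods behind spineflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spineflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineflim)
```

spineflim quantifies the activity of FRET biosensors in dendritic spines
from two-photon fluorescence lifetime imaging (2pFLIM), together with the
two companion measurements of single-spine structural plasticity
experiments: spine volume in femtolitres and the exocytosis component of
surface-receptor FRAP recovery. This vignette explains the models, the
tunable parameters, the synthetic-data generator used for validation, and
the numerical choices the implementation makes.

## The decay model

A FLIM detector histograms the arrival times of single fluorescence
photons within each laser repetition period. When a fraction of donor
fluorophores is bound to an acceptor, FRET shortens their lifetime, and
the population decay is a two-component mixture

$$F(t) = F_0\,\bigl[P_D\,H(t, t_0, \tau_D, \tau_G)
       + P_{AD}\,H(t, t_0, \tau_{AD}, \tau_G)\bigr],$$

where $P_D$ and $P_{AD} = 1 - P_D$ are the amplitude fractions of free and
bound donor, $\tau_D > \tau_{AD}$ the two lifetimes, $t_0$ the pulse
offset, and $H$ is a one-sided exponential convolved with a Gaussian
instrument response of width $\tau_G$:

$$H(t) = \tfrac{1}{2}
  \exp\!\Bigl(\tfrac{\tau_G^2}{2\tau^2} - \tfrac{t-t_0}{\tau}\Bigr)\,
  \mathrm{erfc}\!\Bigl(\tfrac{\tau_G^2 - \tau(t-t_0)}
                             {\sqrt{2}\,\tau\,\tau_G}\Bigr).$$

Evaluated literally, the product overflows when the erfc argument is
large; `irf_convolved_exponential()` therefore uses the scaled
complementary error function with the identity
$\exp(a)\,\mathrm{erfc}(x) = \exp(a - x^2)\,\mathrm{erfcx}(x)$, where
$a - x^2$ collapses to $-(t-t_0)^2/2\tau_G^2$. The scaled erfc itself is
computed from the normal CDF in log space, which is accurate for
arbitrarily large arguments. Agreement with direct numerical convolution
is at the $10^{-8}$ level across the parameter range used in practice
(`tests/testthat/test-decay-model.R`).

### Fitting

Photon counts per channel are Poisson distributed, so `fit_decay()`
maximises the Poisson likelihood (a weighted-least-squares objective is
available via `method = "wls"`; the two agree at high counts). The two
lifetimes are fixed by the sensor calibration — they are measured once per
construct, not per image — and the fit estimates $P_{AD}$, $t_0$,
$\tau_G$ (optionally fixed) and the amplitude $F_0$, which is profiled
out in closed form. The expected curve folds the decay tail of the two
preceding excitation periods back into the 12.5 ns window
(`wrap_periods = 2`), matching periodic pulsed excitation at 80 MHz;
without this the fitted $P_{AD}$ acquires a percent-level bias. Standard
errors come from the observed information matrix; over 100 replicates at
$10^5$ photons the estimator is unbiased to $\pm 0.01$ in $P_{AD}$ and
the $\pm 2\sigma$ interval covers at the nominal rate.

The fit is intended to be *image-wide*: all pixels of a frame are pooled
into one histogram, and the fitted $t_0$ (and $\tau_G$) are reused for
every per-pixel and per-ROI computation in that series.

### Calibration presets

Three donor/acceptor pairs ship as presets: `rab4_egfp_mcherry`
($\tau_D = 2.46$, $\tau_{AD} = 1.10$ ns), `rab10_egfp_mcherry`
($2.60$, $1.10$ ns) and `rab10_mturq2_mvenus` ($4.15$, $1.60$ ns).

## Binding fraction from the mean arrival time

Per pixel or per ROI there are too few photons for a stable curve fit, so
the activity readout uses the mean photon arrival time
$\langle t\rangle = \sum_i t_i c_i / \sum_i c_i$ over the window,
converted to a mean lifetime $\langle\tau\rangle = \langle t\rangle - t_0$
and then to a binding fraction by the closed form

$$P_{AD} = \frac{\tau_D(\tau_D - \langle\tau\rangle)}
  {(\tau_D - \tau_{AD})(\tau_D + \tau_{AD} - \langle\tau\rangle)},$$

which is the exact inverse of the photon-weighted mixture mean
$\langle\tau\rangle = (P_D\tau_D^2 + P_{AD}\tau_{AD}^2) /
(P_D\tau_D + P_{AD}\tau_{AD})$. The round trip holds to $10^{-9}$ across
all presets, and $P_{AD}$ is strictly decreasing in $\langle\tau\rangle$
on $(\tau_{AD}, \tau_D)$. Values outside $[0,1]$ from noisy input are
clamped and flagged — never silently; the singular point
$\langle\tau\rangle = \tau_D + \tau_{AD}$ raises an error.

### Finite-window correction

The closed form assumes the first moment of the *untruncated* decay. Real
arrival times live on a finite window with the tail wrapped by periodic
excitation, which pulls $\langle t\rangle$ down by
$T e^{-(T-t_0)/\tau}/(1 - e^{-T/\tau})$ per component — about 0.16 ns for
$\tau = 2.6$ ns on a 12.5 ns window, i.e. a $P_{AD}$ bias near $+0.05$.
`roi_binding_fraction()` therefore inverts the *window-truncated* forward
model by default: the expected mean arrival time under the wrapped model
curve, evaluated on the histogram's own channel grid (so binning is
treated identically to the data), is a monotone function of $P_{AD}$ and
is solved by bisection. This makes the ROI estimator unbiased under the
same acquisition model that generated the data, while
`binding_fraction_from_mean_lifetime()` keeps the literal closed form;
`correct_truncation = FALSE` selects the uncorrected behaviour, whose
bias the test suite characterises explicitly. Differential readouts
($\Delta P_{AD}$) are nearly insensitive to this choice because the bias
cancels in the baseline subtraction.

Per-pixel lifetime maps (`lifetime_image()`) mask pixels below a photon
floor (default 50 photons) rather than failing.

## Time courses and phase summaries

`binding_fraction_timecourse()` reports the absolute change
$\Delta P_{AD}(t)$ relative to the mean over the baseline window (default:
all pre-stimulus frames), so baseline frames average to zero by
construction. `volume_change_timecourse()` reports
$\Delta V/V(t) = (F(t) - \bar F_{\mathrm{base}})/\bar F_{\mathrm{base}}$
from the summed volume-channel intensity, which is invariant to the raw
intensity scale. `summarize_phases()` averages over the transient
(default 1.3–4 min) and sustained (default 19–31 min; volume-only
protocols conventionally use 20–35 min) windows. Windows are **closed**
intervals — frames exactly on an endpoint are included — and masked
frames are excluded, reducing $n$, never interpolated.
`group_summary()` aggregates per-cell summaries into mean ± SEM and, for
two groups, an equal-variance unpaired two-tailed t test; its type-I
error is calibrated in the test suite.

## Spine volume in femtolitres

The volume estimator normalises the integrated volume-marker intensity of
the spine by the per-pixel intensity of a thick dendrite from the same
cell and multiplies by the PSF volume. Because the dendrite reference is
per *pixel* while the spine signal is integrated over pixels, a factor
$\kappa = 1/(\text{PSF cross-section in pixels})$ is required so that a
structure exactly filling one PSF yields the PSF volume:

$$V_{\text{spine}} = \frac{\sum_{\text{spine}} I}
  {\bar I_{\text{dendrite}}} \cdot
  \frac{V_{\mathrm{PSF}}\, A_{\text{pixel}}}{A_{\mathrm{PSF}}}.$$

This normalisation is validated by recovery of simulated spines of known
volume (0.05–0.5 fL, within 2% noiseless) rather than asserted. The
dendrite reference statistic is the mask mean by default (`"peak"`
selects the brightest pixel); the PSF volume and cross-section are
configuration parameters (defaults 0.08 fL and 0.13 µm², typical for a
1.0-NA two-photon system at ~920 nm) — no value is universal, and the
simulator uses the same numbers, so recovery tests are self-consistent.
The volume marker is the acceptor channel; a configured donor
bleed-through fraction can be subtracted first. Bleed-through has little
effect on *fractional* volume changes because both channels share the
volume time course.

## FRAP: isolating the exocytosis component

A surface-only reporter recovers after photobleaching both by new
exocytosis and by lateral diffusion into an enlarging spine. With
$F_o = fS$ the fluorescence immediately after the bleach ($f$ = surface
density, $S$ = spine surface area), the recovery decomposes as
$\Delta F/F_o = \Delta F_t/F_o + \Delta S/S$, and with
$S \propto V^{2/3}$ the trafficking component is

$$\Delta F_t/F = \Delta F/F - (\Delta V/V)^{2/3}.$$

`diffusion_corrected_recovery()` implements this with two documented
choices:

* **Reference convention.** The algebra requires changes relative to the
  post-bleach $F_o$; the conventional display axis is $F/F_0$ with a
  pre-bleach baseline. Both are available (`Fo_convention = "post"` is
  the default because it is what the derivation defines).
* **Surface rule.** The literal $(\Delta V/V)^{2/3}$ is the default. It
  is undefined for $\Delta V/V < 0$ (noisy frames near zero volume
  change); such frames are returned `NA` with a warning, never silently
  clamped or made complex. The geometrically exact alternative for a
  dilating sphere, $\Delta S/S = (1+\Delta V/V)^{2/3} - 1$, is available
  as `surface_mode = "sphere"` and is defined for all
  $\Delta V/V > -1$; noisy-ensemble validation uses it on both the
  generator and the correction for exactly this reason.

On noiseless series built with the same surface rule the correction
recovers the ground-truth exocytosis component to floating-point
round-off; with flat volume it reduces to the identity on
$\Delta F/F$. Frames inside the bleach and uncaging intervals are marked
and excluded from summaries; traces must share timestamps exactly — no
resampling.

The default protocol is five baseline frames at 1 min intervals, a 2 min
whole-dendrite bleach ending at $t = 0$, a 1 min stimulus from $t = 0$,
and eight recovery frames at 1 min intervals.

## The synthetic-data generator

Every estimator above is validated against simulated data with known
ground truth; no external download is needed.

**Photon level.** Arrival times are drawn from the mixture model with one
subtlety: a component with amplitude fraction $P$ and lifetime $\tau$
emits photons in proportion to $P\tau$ (amplitude weights the peak, not
the photon total). This makes the simulated mean arrival time consistent
with the closed-form inversion — the mixture-moment invariant is tested
at $10^6$ photons. Photons beyond the 12.5 ns window (256 channels,
80 MHz excitation) are wrapped by default (periodic excitation); a clip
mode drops them and reports the count. The IRF width default is 0.2 ns, a
realistic PMT/TCSPC response; detector background defaults to zero. All
generators require an explicit seed and restore the caller's RNG state.

**Image level.** The default scene is a 32 × 32 px field (0.125 µm
pixels) holding a dendrite band (thicker than the PSF), a stimulated
spine (0.10 fL) and an adjacent spine (0.12 fL). Donor photons are
budgeted per structure in proportion to visible donor content
(concentration × image-sampled volume, scaled by the volume multiplier),
and the acceptor channel is rendered with the same PSF geometry the
volume estimator assumes, plus 5% multiplicative Gaussian noise (an
image-level stand-in for shot noise) and optional donor bleed-through.

**Dynamics presets.** `profile_rab10()` encodes persistent inactivation:
a $\Delta P_{AD} = -0.10$ step at the stimulus, held to the end of the
recording, restricted to the stimulated spine. `profile_rab4()` encodes
transient activation: a $+0.10$ pulse decaying with a 3 min constant.
Both carry the structural plasticity volume transient (×3.5 peak during
the first minute, decaying to a ×1.8 sustained plateau with a 4 min
constant). Baseline binding fractions (0.25 and 0.15) are plausible
resting values for the respective sensors. The frame grid is 50 frames
at 40 s with five pre-stimulus baseline frames; `profile_nmda()` emulates
a 2 min bath application that shifts every compartment, after 6 min of
baseline at 1 min intervals; `profile_null()` is the negative control.

**What the generator does not emulate.** Uniform fluorophore
distribution within each structure (no puncta), no drift or focus
changes, no donor photobleaching during sensor imaging, no detector
afterpulsing or dark counts by default, noise at the image level rather
than a full optical model. Passing tests therefore demonstrate
correctness of the *analysis* under the stated acquisition model, not
robustness to every artefact of real microscopy.

## Problem sizes and reproducibility

The validation suite uses sizes chosen to exercise the estimators at
realistic photon budgets: image-wide fits at $10^5$–$10^6$ photons,
ROI recovery at $10^4$–$10^5$ photons per frame, 20-seed ensembles of
50-frame movies at $2\times10^5$ photons/frame for the end-to-end
pipeline, and 50-seed FRAP ensembles. `scripts/acceptance.R` recomputes
the same quantities from scratch for any seed. Every simulation is
bit-reproducible from (configuration, seed); pipeline outputs are
byte-identical across reruns, and the run manifest records the
configuration hash, seed and package version (deliberately no
timestamps).

## Known limitations

* Two decay components only; multi-exponential decays, anisotropy and
  phasor analysis are out of scope.
* The ROI estimator assumes the image-wide $t_0$ and $\tau_G$ apply to
  every pixel (true for a single detector channel).
* The mean-arrival estimator clamps out-of-range binding fractions at
  low photon counts; the flag should be monitored when ROIs are dim.
* Spine volume accuracy inherits the PSF-volume calibration; the
  estimate is exact only relative to that constant.
* The FRAP correction assumes the surface density $f$ is uniform along
  the bleached dendrite and that the volume marker tracks spine volume
  linearly.
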