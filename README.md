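# spineflim

Quantification of FRET-sensor activity, spine volume and receptor
exocytosis from two-photon fluorescence lifetime imaging (2pFLIM) of
dendritic spines.

Single-spine structural plasticity experiments read out three things at
once: the activity of a signalling protein via a FLIM-FRET sensor, the
spine volume via a cytosolic marker, and (in FRAP experiments) the
exocytosis of surface receptors. spineflim implements the full analysis
chain for all three, plus a synthetic time-correlated single-photon
counting (TCSPC) simulator with known ground truth so that every stage is
testable end to end.

## The models

**Decay fitting.** Photon arrival-time histograms follow an
IRF-convolved two-component decay

> F(t) = F₀ [P_D H(t, t₀, τ_D, τ_G) + P_AD H(t, t₀, τ_AD, τ_G)],

with H a one-sided exponential convolved with a Gaussian pulse response
of width τ_G (evaluated via the scaled complementary error function for
numerical stability). `fit_decay()` maximises the Poisson likelihood of
the counts with the lifetimes τ_D, τ_AD fixed by the sensor calibration,
returning a classed model object with the usual `coef`, `summary`,
`predict`, `residuals`, `plot` and `simulate` methods.

**Binding fraction.** Per ROI, the mean photon arrival time ⟨t⟩ gives
⟨τ⟩ = ⟨t⟩ − t₀ and the bound-donor fraction

> P_AD = τ_D(τ_D − ⟨τ⟩) / [(τ_D − τ_AD)(τ_D + τ_AD − ⟨τ⟩)],

with an optional (default) finite-window correction that inverts the
wrapped forward model instead of the idealised closed form.

**Spine volume.** Integrated spine intensity, normalised by thick-
dendrite per-pixel intensity and scaled by the PSF volume, gives volume
in femtolitres.

**FRAP correction.** For a surface-only reporter, the trafficking
component of recovery is ΔF_t/F = ΔF/F − (ΔV/V)^(2/3), separating
exocytosis from lateral diffusion into an enlarging spine.

See `vignettes/spineflim-methods.Rmd` for assumptions, parameters and
numerical choices.

## Worked example

```r
library(spineflim)

## fit a simulated histogram (200k photons, 30% bound donor)
truth <- decay_model(PAD = 0.30, calibration = "rab10_egfp_mcherry",
                     t0 = 1.2, tauG = 0.2)
h   <- simulate_histogram(truth, 2e5, seed = 42)
fit <- fit_decay(h, "rab10_egfp_mcherry")
summary(fit)
#> Decay fit summary
#>        Estimate Std. Error
#> F0   4577.88910    21.7752
#> PAD     0.31119     0.0061
#> t0      1.20050     0.0023
#> tauG    0.20157     0.0021
#> Fixed lifetimes: tauD = 2.60 ns, tauAD = 1.10 ns
#> Deviance 251.5 on 252 df; 200000 photons; <tau> = 2.225 ns
```

The fitted binding fraction (0.311 ± 0.006) recovers the simulated truth
(0.30); the deviance ≈ degrees of freedom says the Poisson model fits.

```r
## end-to-end: persistent-inactivation preset, one seed
res <- run_pipeline(list(preset = "rab10", seed = 7), quiet = TRUE)
res$summaries$dpad_spine_stim
#> Phase summary (spine_stim):
#>   transient [1.3, 4] min: -0.08948 +/- 0.0076 (n = 5)
#>   sustained [19, 31] min: -0.09915 +/- 0.007 (n = 16)
res$summaries$volume_spine_stim
#> Phase summary (spine_stim):
#>   transient [1.3, 4] min: 1.947 +/- 0.14 (n = 5)
#>   sustained [19, 31] min: 0.8002 +/- 0.0084 (n = 16)
```

The stimulated spine's binding fraction drops by ≈0.10 in both phases
(the preset's ground truth is a held −0.10 step) while its volume rises
×2.9 transiently and settles at ×1.8 (ΔV/V of 1.95 and 0.80 over the two
windows).

```r
## FRAP: isolate the exocytosis component (noiseless demonstration)
tr  <- frap_ground_truth()
s   <- simulate_frap_series(tr, noise_sd = 0, seed = 1)
out <- diffusion_corrected_recovery(normalize_frap(s))
out
#> Corrected FRAP recovery (literal surface rule, post-bleach Fo)
#>   exocytosis component at last frame: 4.487
```

The corrected trace equals the simulator's exocytosis ground truth to
round-off (4.487 = 4.5·(1 − e^(−7/1.2))).

A command-line interface wrapping the same functions lives at
`inst/cli/spineflim.R` (verbs `simulate`, `fit`, `quantify`, `frap`,
`run`).

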