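# cardiotherm

Real-time cardiac MR thermometry and thermal dosimetry in R.

Catheter-based radiofrequency ablation (RFA) treats cardiac arrhythmia by
heating myocardium, but the operator normally cannot see the lesion as it
forms. MR thermometry closes that gap: on a phase-sensitive gradient-echo
acquisition the water proton resonance frequency shifts with temperature, so
phase differences between dynamic frames encode temperature change, and the
accumulated time–temperature history predicts the necrosed area.
`cardiotherm` implements that processing chain for 2D+time cardiac series,
together with a synthetic dynamic-MR phantom so every stage can be validated
quantitatively without scanner data. It is aimed at interventional-MR and
image-analysis researchers who need a reference implementation of the
pipeline, its correction steps, and its dosimetry.

## The model

**PRFS thermometry.** Temperature change is recovered per pixel from the
corrected, unwrapped phase:

    ΔT = (φ_t − φ_ref) · k,     k = (2π · γ/2π · α · B0 · TE)⁻¹

with γ/2π = 42.58 MHz/T, α = −0.0094 ppm/°C, B0 the field strength and TE
the echo time. At 1.5 T and TE = 18 ms, k = −14.73 °C/rad (heating lowers
the phase).

**Motion and susceptibility correction.** Residual in-plane motion is
estimated on magnitude images by variational (Horn–Schunck-type) optical
flow; the per-frame fields are compressed into a PCA basis. Breathing also
modulates the B0 field, so registered phases still carry a motion-dependent
susceptibility phase: over the first 30 frames a per-pixel linear model from
the motion-basis coefficients to the phase is learned, then used to correct
all later frames. A spatially uniform, slowly varying field drift (several
°C-equivalent over minutes if ignored) is removed per frame as the median
phase offset over a stable region, and the temperature series is smoothed by
a causal order-2 Butterworth low-pass (cutoff 0.14 Hz).

**CEM43 thermal dose.** Absolute temperature T = T_ref + ΔT accumulates
cumulative equivalent minutes at 43 °C with the standard branch factors
(×2 per °C above 43 °C, ×4 below):

    TD += R(T) · dt / 60,   R(T) = 2^(T−43)  (T ≥ 43),   4^(T−43)  (T < 43)

240 equivalent minutes (constant 43 °C for 240 min) is the lethal threshold;
maps are displayed in normalized units where 1 = lethal. Because thermometry
noise propagates exponentially into dose, the dose is attenuated by the
pre-ablation temperature uncertainty σ_T (computed over 20 pre-RF frames):

    TD_corrected = TD · exp(−0.5 · (ln 2 · σ_T)²)

The lethal lesion is the 8-connected supra-threshold component at the
catheter tip; its largest/smallest dimensions are principal-axis extents in
mm.

**Lesion concordance.** The package embeds a table of 12 in-vivo sheep
ablations (power, duration, energy, and paired lesion dimensions from
thermal-dose maps and post-ablation T1-weighted imaging) and computes the
agreement statistics between the two measurements: Pearson correlation,
regression of TD on T1-w dimensions, and Bland–Altman bias with 95% limits
of agreement.

## Worked example

Simulate an ablation-style acquisition (respiratory motion, susceptibility
coupling, drift, noise at SNR 80, a 60 °C hotspot with RF on at frame 50 for
40 s) and run the full pipeline:

```r
library(cardiotherm)

cfg <- phantom_config(grid_size = c(48, 48), n_frames = 110,
                      heat_peak = 60, snr = 80, seed = 1)
g   <- generate_series(cfg)
res <- run_pipeline(g$series, pipeline_config(hotspot = c(24.5, 24.5)))
res
#> Cardiac thermometry result: 61 temperature maps (frames 50-110)
#>   max dT 53.7 degC; peak corrected dose 1e+11 x lethal
#>   lesion: 8.0 x 8.0 mm (48.6 mm^2)
```

The peak measured rise is 53.7 °C (the 60 °C hotspot times its exponential
heating envelope at RF-off), the centre of the hotspot exceeds the lethal
threshold by many orders of magnitude (dose is exponential in temperature),
and the extracted lesion measures 8.0 × 8.0 mm — within one pixel (0.8 mm)
of the lesion obtained by dense integration of the known ground-truth
temperature field. `glance(res)` returns the same summary as a one-row
tibble (mean σ_T here: 0.66 °C; excluded-pixel fraction 2.2%).

The embedded ablation table and its agreement analysis:

```r
st <- agreement_stats(load_table1())
st
#> Lesion-dimension agreement (N = 24 pairs)
#>   Pearson r        : 0.915
#>   TD ~ T1-w        : slope 1.056, intercept 0.060 mm
#>   Bias (TD - T1-w) : 0.46 +/- 1.08 mm
#>   95% limits       : [-1.66, 2.58] mm
autoplot(st)                  # Bland-Altman plot
autoplot(st, type = "scatter")
```

A thin CLI over the same functions is installed at
`inst/cli/cardiotherm` (subcommands `simulate`, `run`, `dose`, `lesion`,
`concordance`, `report`; YAML config, NIfTI/CSV/JSON output).

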