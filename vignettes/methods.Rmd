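---
title: "Methods: motion-compensated cardiac MR thermometry and CEM43 dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-compensated cardiac MR thermometry and CEM43 dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotherm)
```

This vignette documents the models implemented in `cardiotherm`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic phantom does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The processing chain

Dynamic cardiac thermometry acquires one multi-slice phase-sensitive image
set per heartbeat while radiofrequency (RF) energy is delivered through a
catheter. Each 2D slice is processed independently and strictly in
acquisition order — every output for frame $t$ depends only on frames
$\le t$, so the chain can run during the intervention. Per frame:

1. **Motion estimation** on the magnitude image against the first frame.
2. **Projection onto a motion basis** learned on the early frames
   (denoising of the per-frame flow).
3. **Phase registration** using the denoised field.
4. **Temporal unwrapping** of the registered phase.
5. **Susceptibility correction**: subtract the motion-predicted phase.
6. **Drift correction**: subtract a frame-wide scalar.
7. **PRFS conversion** to temperature change.
8. **Temporal low-pass filtering** (causal Butterworth).
9. **CEM43 dose accumulation** and, at the end, uncertainty correction and
   lesion extraction.

## PRFS temperature conversion

$\Delta T = (\varphi_t - \varphi_{ref})\,k$ with
$k = (2\pi\,\tfrac{\gamma}{2\pi}\,\alpha\,B_0\,TE)^{-1}$,
$\gamma/2\pi = 42.58$ MHz/T and $\alpha = -0.0094$ ppm/°C. At $B_0 = 1.5$ T
and $TE = 18$ ms, $k = -14.73$ °C/rad. The sign is kept: heating lowers the
phase, and the phantom writes its heating phase with the same convention so
that recovery is sign-consistent end to end.

The per-pixel phase series is unwrapped **temporally** (inter-frame changes
wrapped into $(-\pi, \pi]$ and accumulated). This is valid because even fast
RF heating moves the phase by well under $\pi$ between consecutive 1 s
frames (a few °C/frame against $|k| \approx 15$ °C/rad). Spatial unwrapping
is deliberately not attempted; static wraps at strong susceptibility
interfaces (heart–liver–lung) remain and surface as high-$\sigma_T$ pixels,
which the exclusion rule (below) removes.

## Motion correction

Optical flow is a Horn–Schunck-type variational solver: Gaussian
pre-smoothing (σ = 1 px), a 3-level coarse-to-fine pyramid, and Jacobi
iterations (default 100/level) of the regularised normal equations. The
`smoothness` weight defaults to 0.2, chosen on translation oracles (a known
3-pixel shift is recovered to within 0.02 px; smaller weights admit noise,
larger ones bias the magnitude of recovered motion downward). The
displacement convention is `registered(x) = moving(x + d(x))`, so `warp()`
resamples a moving frame onto the reference anatomy; phases are warped
through (cos, sin) to keep wrap discontinuities out of the interpolation.

Per-frame fields over the learning window are compressed by PCA (default 2
components). During the intervention each fresh field is projected onto the
basis and reconstructed rank-limited before use — respiratory motion is
essentially low-dimensional, so this denoises the registration without
violating causality. The reference position is the first frame.

## Susceptibility model and drift

Breathing changes the B0 field, so registered phases still vary with the
respiratory state. Over the first `n_learn = 30` frames the package fits,
per pixel, ordinary least squares of unwrapped registered phase on the
motion-basis coefficients. The coefficient maps predict the
motion-dependent phase of every later frame, which is subtracted (the
intercept — the baseline phase — is untouched). If the motion coefficients
are degenerate (e.g. a motionless acquisition) the fit falls back to
intercept-only with a warning; the correction then subtracts nothing, which
is the right behaviour when there is no motion to model.

Scanner drift is modelled as a spatially uniform phase offset per frame,
estimated as the **median** of (corrected phase − reference phase) over a
stable mask and subtracted frame-wide. The default mask excludes a
10 mm-radius disc around the declared hotspot (about four hotspot widths);
without a declared hotspot the median over all pixels is used, which is
robust to a compact heated region. A first-order planar drift would be a
straightforward extension; the uniform scalar removes a 5 °C-equivalent
drift over 150 s to below 0.3 °C residual on an unheated phantom, which is
the scale that matters here.

The reference phase is the mean corrected phase over frames
`n_learn + 1 … rf_start_frame − 1` (31–49 under the defaults): averaging
~19 frames reduces reference noise by a factor ~4.4. Temperature maps are
emitted from `rf_start_frame` onward; earlier frames are the learning and
baseline material. This also keeps the pipeline causal — emitting
temperatures for the frames that themselves define the reference would make
truncation non-reproducible.

Temperature maps are finally filtered per pixel by a causal order-2
Butterworth low-pass, cutoff 0.14 Hz at the 1 Hz frame rate (the filter
order is a package choice; only the cutoff is externally prescribed). The
filter has unit DC gain; its registers are primed to the steady state of the
first emitted frame so the series does not start with a spurious transient.
Streaming updates are direct-form-II transposed with per-pixel state.

## Stability statistics and exclusion

$\mu_T$ and $\sigma_T$ are per-pixel temporal mean and sample standard
deviation of the emitted temperature series. Pixels with
$\sigma_T > 7$ °C are excluded from ROI statistics (the rule used to remove
phase-wrap-degraded pixels in practice). The dose-correction input
$\sigma_T$ is computed over the `sigma_baseline_window = 20` frames
immediately before RF, on **unfiltered** temperatures (as the std of
corrected phase × |k|, which is reference-free). Unfiltered is the
conservative choice: filtering would shrink $\sigma_T$ and therefore weaken
the dose attenuation.

## Thermal dose

The CEM43 integrand uses branch factors 2 (above 43 °C) and 4 (below);
dose is accumulated with a causal rectangle rule — the current frame's
temperature held over $[t, t + dt)$ — with $dt$ the frame interval. The
lethal threshold is 240 equivalent minutes, and maps are thresholded in
normalized units (lethal = 1). Absolute temperature is
$T_{ref} + \Delta T$ with $T_{ref}$ = 37 °C by default (rectal temperature
in practice).

Numerical behaviour of the rectangle rule: against dense integration of the
same curve (linear interpolation between frames, `true_dose()` with many
substeps) the streaming integrator is *exact* at one substep by
construction, and agrees within ~0.5% for heating rates up to 3 °C/s; the
error grows with the heating rate (≈4% for the default 75 °C/15 s-rise
phantom) because dose is exponential in temperature. Both bounds are
checked in the tests.

The uncertainty correction multiplies the dose by
$e^{-0.5(\ln 2\,\sigma_T)^2}$, which is 1 at $\sigma_T = 0$, 0.58 at
1.5 °C, and effectively suppresses dose ($<10^{-5}$) at the 7 °C exclusion
level — dose claims are only made where thermometry is trustworthy. The
correction commutes with thresholding only for spatially uniform
$\sigma_T$; the package applies it before thresholding.

Lesion extraction keeps the 8-connected supra-threshold component containing
(or nearest to) the declared hotspot; other components are discarded and
counted in the log. An empty mask is a valid "no lesion" outcome, reported
explicitly rather than raised as an error (ablations with poor
electrode–tissue contact genuinely produce none). Dimensions are
principal-axis extents of pixel-centre coordinates (max − min projection
plus one pixel spacing, so a single pixel measures one pixel across). For
compact blobs these coincide closely with ruler/caliper measurements and
are reproducible, which is why they were preferred over Feret diameters —
the measurement was not operationally defined externally.

## The synthetic phantom

`generate_series()` emulates, with analytic ground truth:

- a smooth soft-edged anatomy at nominal intensity 1 with sinusoidal
  texture (so optical flow has gradients), evaluated analytically at
  displaced coordinates — motion warping is exact, with no interpolation
  error in the simulation itself;
- periodic in-plane respiratory translation along the head–foot axis,
  default 5 mm peak at 24 breaths/min. The 5 mm default is the in-plane
  residual: measured breathing amplitudes (~9 mm) are dominated by the
  through-plane component, which slice tracking handles upstream and is
  out of scope here;
- susceptibility phase **linear** in the respiratory displacement with a
  planar gain-map gradient (±0.05 rad/mm across the FOV, i.e. up to ~±3.7 °C
  equivalent at 5 mm) — matching the linearity assumption of the
  correction model;
- spatially uniform drift, default 0.0023 rad/s ≈ 5 °C-equivalent over
  150 s at $k = -14.73$ °C/rad;
- a Gaussian hotspot (σ = 2.5 mm) with separable envelope
  $1 - e^{-t/\tau_{rise}}$ during RF and $e^{-t/\tau_{decay}}$ after
  (defaults 15 s / 30 s), peak 75 °C, RF on at frame 50 for 40 frames —
  an analytic stand-in for bioheat diffusion, not a PDE solution;
- complex Gaussian noise (Rician magnitude), σ = 1/SNR of the nominal
  tissue intensity, so per-pixel phase noise is ≈ 1/(SNR·A) in the
  high-SNR regime.

What it does **not** emulate: through-plane motion, cardiac contraction,
spatial phase wraps at organ interfaces, the hypointense catheter artifact,
blood flow, perfusion-dependent cooling, or EPI-specific artifacts
(ghosting, distortion). Passing tests therefore demonstrate correctness of
the *processing* under the modelled physics — they do not certify
performance on scanner data, where those unmodelled features dominate the
failure modes.

Determinism: the same configuration and seed reproduce the series bit for
bit; changing the seed changes only the noise realisation, never the ground
truth.

## Problem sizes and defaults

The default phantom is 96 × 96 pixels at 0.8 mm (a heart-sized field of
view; full-chest reconstructions are larger but carry no additional
structure relevant to the algorithms), 250 frames at 1 s. Tests and the
validation suite run on 12–64 px grids and 60–250 frames, which keeps the
whole suite in the minutes range while leaving every algorithmic path
exercised at realistic physical scales (pixel spacing, SNR, drift and
heating rates are never scaled down).

## Known limitations

- The susceptibility model is linear in two motion coefficients; breathing
  patterns outside the learned subspace (e.g. pattern changes mid-series)
  are not corrected.
- The drift model is spatially uniform per frame.
- Horn–Schunck flow assumes brightness constancy; strong through-plane
  content changes would bias it.
- The streaming dose rectangle rule overestimates slightly on cooling and
  underestimates on heating; errors are at the percent level for cardiac
  RFA heating rates but grow exponentially with per-frame temperature
  steps.
- Lesion dimensions assume a compact, roughly convex lethal region;
  principal-axis extents of a strongly concave lesion would differ from
  caliper measurements.
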