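---
title: "Echo-shifted multi-echo GRE simulation and fitting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo-shifted multi-echo GRE simulation and fitting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmgre)
```

## The problem

Multi-echo gradient-echo (mGRE) sequences quantify T2\* by sampling the
signal decay at a train of echo times. Brain tissue (T2\* roughly
30--60 ms at 3 T) is well served by echo trains reaching ~70 ms, but
cerebrospinal fluid decays an order of magnitude more slowly, so accurate
CSF T2\* requires echo times of hundreds of milliseconds -- normally at the
cost of a much longer TR and scan time.

Echo shifting avoids that cost. In a multislice acquisition each slice owns
a sub-TR interval of length TR divided by the slice count. A pair of
unbalanced "additional" gradients with area ratio $-1:+2$ dephases the
spins at the end of their own sub-TR and rephases them during the *next*
slice's interval, where a second block of echoes (the *shifted* echoes) is
read out at long TE. The next slice's freshly excited spins are dephased by
the same gradients and do not contaminate the shifted readout; after its
shifted block each slice's magnetization is progressively spoiled. The
total scan is prolonged by only one sub-TR.

The additional gradients also diffusion-weight the shifted echoes. Their
area is parameterized as $K$ times the slice-rephasing gradient area, so
$K$ is simultaneously the echo-shift and the diffusion-sensitivity knob:
the toolkit computes the resulting b-value exactly from the gradient
waveform, and the voxelwise fit estimates a 1-D diffusivity $D$ alongside
T2\*.

## Forward signal model

A voxel's complex signal at echo time $TE_n$ is the spoiled-GRE steady
state with off-resonance, diffusion attenuation and complex Gaussian noise:

$$ s(TE_n) = M_0 \sin\alpha \, \frac{1 - e^{-TR/T_1}}{1 - \cos\alpha \,
e^{-TR/T_1}} \; e^{-TE_n/T_2^*} \, e^{i(\phi_0 + 2\pi \Delta f \, TE_n)}
\, e^{-b(TE_n) D} + \varepsilon(0, \sigma^2). $$

The single-RF-per-slice interleaving keeps the steady state identical to a
spoiled GRE (no signal loss from multiple pulses per effective TR). The
same steady-state expression quantifies the diminishing return of raising
TR instead of shifting echoes: for $T_1 = 4300$ ms, doubling TR from 3000
to 6000 ms at the respective Ernst angles raises the amplitude by only
34%:

```{r}
a3 <- steady_state_amplitude(1, ernst_angle(3000, 4300), 3000, 4300)
a6 <- steady_state_amplitude(1, ernst_angle(6000, 4300), 6000, 4300)
100 * (a6 / a3 - 1)
```

The magnitude model used for fitting folds the steady state into the
intensity at TE = 0 and adds the bipolar-readout modulation:

$$ s(TE_n) = M_0 \, e^{-TE_n/T_2^*} \, e^{-b(TE_n) D} \, e^{(-1)^n \delta}, $$

with the $(-1)^n$ sign taken from each echo's readout polarity.

## Sequence timing and gradient model

All lobes are symmetric trapezoids laid out on a 0.01 ms gradient raster;
amplitudes are solved so that each lobe's *discrete* area is exact, which
makes the zeroth-moment cancellation at echo centers exact in the sampled
integral too. Echo-train slots are spaced by the echo spacing dTE; each
navigator (a phase-encode-free readout used for the phase correction)
occupies exactly one slot. This slot-counting convention reproduces
published-protocol prompt-block TEs to raster rounding (e.g. the in vivo
preset's 43rd echo at 66.21 ms for a printed 66.18 ms). Shifted echoes are
offset by one sub-TR plus the duration of the first additional-gradient
lobe, which the package derives from the $K$-scaled area and the slew-rate
limit; the derived TEs land within about 2% of the preset's nominal
values.

Parameters that the protocol does not pin down are fixed, documented
defaults of the package:

* `max_grad` 30 mT/m and `slew_rate` 200 mT/m/ms -- representative 3 T
  whole-body hardware values; they set ramp times and the echo-shift lobe
  duration.
* `rf_dur` 2.56 ms and `rf_tbw` 2.7 -- the excitation pulse. The
  time-bandwidth product fixes the slice-rephasing area
  $A_s = \mathrm{TBW}/(2 \bar\gamma \Delta z)$ that $K$ scales, and hence
  every b-value. A TBW of 2.7 is typical of short vendor excitation
  pulses and places the $K = 10$, 2 mm-slice shifted-echo b-value near
  230 s/mm^2, inside the 180--250 s/mm^2 range the bundled in vivo preset
  is meant to represent; a high-TBW pulse (e.g. 4) would roughly double
  that, so the default is part of the package's calibration and is
  deliberately exposed in the protocol.
* The additional gradients ride on the slice axis by default (the axis
  also used by the bundled presets); `addgrad_axis` switches them.

b-values are computed as $b(TE_n) = \gamma^2 \int_0^{TE_n}
\left(\int_0^t G\,dt'\right)^2 dt$ over the read and slice axes, phase
encoding excluded; for shifted echoes the integral spans both sub-TR
intervals the spins traverse. The integrator is validated against the
Stejskal--Tanner closed form $\gamma^2 G^2 \delta_g^2 (\Delta_g -
\delta_g/3)$ on rectangular pulsed-gradient pairs (relative error below
$10^{-3}$ at the default raster). Spins are called "dephased" when their
zeroth moment exceeds the standard crusher criterion of $2\pi$ phase
dispersion across one slice thickness.

## Digital phantom and what it does (not) emulate

`build_figure2_phantom()` arranges five rectangular, axis-aligned blocks
-- gray matter, white matter, putamen, globus pallidus, CSF -- on a
zero-signal background scaled to the protocol matrix. The default tissue
values are literature-typical 3 T numbers (e.g. CSF T1 4300 ms, T2\*
1800 ms, D 3 um^2/ms; white matter 850/50/0.7); they are simulation
inputs, not reference values, and every test that matters is invariant to
their exact choice. Noise is specified as an SNR relative to the white
matter signal at the first echo (default SNR 50).

The phantom is a single 2-D slice with voxelwise mono-exponential decay:
no Bloch time-stepping, no susceptibility field, no partial volume, no
flow or perfusion (so no pseudo-diffusion component), no multi-compartment
decay, and a single receive coil. Multislice physics enters only through
the timing and moment analysis of the gradient model. Passing tests
therefore demonstrate the correctness of the sequence timing, the
correction algebra and the estimator -- not robustness to the omitted
in vivo effects.

## K-space corruption and the two-step navigator correction

Physiological field fluctuation is modeled as a spatially uniform
per-shot frequency offset $\Delta f_0(p)$ (sinusoid + drift + optional
jitter), which multiplies the acquired line $p$ of echo $n$ by
$e^{i 2\pi \Delta f_0(p) TE_n}$ -- exactly the term the correction
removes; an optional component acting only during the shifted block
emulates slow variation along the train that the first navigator cannot
see.

The correction works in hybrid $(x, k_y)$ space after a 1-D transform
along the readout. Step 1 takes the phase of the prompt-block navigator
on each line relative to the first acquired line and removes it from every
readout -- prompt, shifted and navigators alike -- scaled by
$TE_n/TE_{nav1}$. (Correcting the first navigator by itself, scale factor
one, zeroes its line-to-line phase and makes the step idempotent.) Step 2
repeats this with the already-corrected shifted-block navigator and
applies the result to shifted echoes only. Phase differences are computed
as the argument of conjugate products, which avoids branch-cut unwrapping
but is valid only for differences below $\pi$ per comparison -- with a
~210 ms shifted-navigator TE this bounds the tolerable shifted-block-only
fluctuation to roughly 1 Hz, a deliberate limitation. For noisy data an
SNR-gated fallback replaces phase estimates at positions whose navigator
SNR is below the mean by the median over the above-mean positions.

On noiseless, model-consistent corruption the two-step correction is
exact to floating-point (normalized RMSE ~1e-16 against the
fluctuation-free reference); on noisy data its effect is tracked with a
ghost-energy metric (image energy outside the object support).

## Fitting: Rician likelihood, initialization, model comparison

Magnitude data are Rician; fitting magnitudes as if Gaussian overestimates
decay constants where the tail of the train is at the noise floor. The
default estimator maximizes the Rician likelihood with $\sigma$ held
fixed at the background estimate (four corner ROIs of 400 voxels,
$\hat\sigma = \text{mean}/\sqrt{\pi/2}$ under Rayleigh statistics; a
second-moment variant is available). $\log I_0$ and $I_1/I_0$ switch to
asymptotic series above argument 50, where the exact Bessel evaluation is
slow and the series is accurate to ~1e-8.

Optimization is bounded quasi-Newton (L-BFGS-B) with analytic gradients.
Initialization is a log-linear fit on the prompt echoes for $(M_0, T_2^*)$
and a shifted/prompt block log-ratio for $D$; a fixed three-point
multi-start on T2\* ($\times 1/3, 1, \times 3$) guards against the shallow
ridge that couples $M_0$, T2\* and $D$. Bounds are T2\* in [1, 5000] ms,
$D$ in [0, 10] um^2/ms, $|\delta| < 1$. Everything is deterministic given
the data and settings.

The bipolar modulation $\delta$ is normally estimated by the iterative
correction: fit the $\delta$-free model, synthesize $\delta$-free images,
pick the $\delta$ minimizing the discrepancy between demodulated data and
synthesis, demodulate, refit (tolerance $10^{-4}$, at most 10 iterations).
It is a single global scalar by default -- the modulation is a property of
the readout, not of tissue -- with a per-voxel variant available.
Simulation fits exclude $\delta$ by default, since simulated data are
generated without readout-related modulation.

Fits with and without the diffusion term are compared per voxel by the
small-sample corrected AIC, $\mathrm{cAIC} = -2\log L + 2k +
2k(k+1)/(n-k-1)$, the simpler model winning ties; on the phantom the
diffusion model is preferred essentially everywhere in CSF and rarely in
white matter, which is the expected spatial pattern for a
high-diffusivity, slow-decaying compartment.

## The simulation grid

`run_grid()` reproduces the simulation-study design: echo counts
{24, 32, 64} x K {4, 8, 10, 12, 16} x six shifted-echo fractions from 0
to 5/6, ten replicates per cell, SNR 50, TR 1200 ms at flip 75 deg, with
each cell's slice count maximized for its readout block and infeasible
cells skipped and recorded. Each replicate simulates and fits one noisy
voxel per tissue region with the exact train and b-values of that cell;
region means and standard deviations are taken over replicates. This
voxel-replicate design was chosen over fitting full images in every cell
because the comparison is carried by the statistics of voxelwise fits,
not by image resolution; the full image pipeline (phantom, k-space,
correction, `fit_map()`) is exercised separately. At these sizes the full
default grid (90 cells, 9000 fits) runs in about one minute on one CPU.

Two monotone trends summarize the K dependence at 64 echoes, one third
shifted: the noiseless CSF shifted-echo signal strictly decreases with K
(larger area, more attenuation and later TEs), and the replicate standard
deviation of fitted CSF diffusivity drops from K = 4 to K = 16 (roughly
tenfold at these settings) -- larger additional gradients buy D precision.

## Problem sizes and reproducibility

The bundled checks use a 64 x 64 matrix for image-domain work, 512 voxels
for the recovery grid (T2\* from 30 to 2000 ms crossed with D from 0 to
3 um^2/ms, 16 replicates per cell), 500 voxels for the Gaussian-vs-Rician
comparison, 170 per K for the no-diffusion bias, and 20 seeded repeats for
the ghost-energy ensemble; these sizes give stable medians and orderings
while keeping a full run at desk scale. All stochastic stages take
explicit integer seeds, every pipeline stage writes a manifest (settings,
seeds, version, output checksums), and rerunning any stage with the same
inputs reproduces its outputs bit-identically.

## Known limitations

* Diffusivity is encoded along a single axis (the additional-gradient
  axis); it is not a rotationally invariant measure and no multi-direction
  scheme is provided.
* Flow and intravoxel incoherent motion are absent from both the
  simulation and the fit model; in real CSF they inflate the apparent
  diffusivity and shorten apparent T2\* regionally.
* The phase correction addresses a global (spatially uniform) frequency
  term only, and phase differences must stay below pi per comparison.
* Short-T2\* tissues lose their shifted echoes to decay, so their D is
  poorly determined at any K; that is a property of the acquisition, not
  of the estimator.
* Single coil, Cartesian, fully sampled k-space; no parallel imaging or
  partial Fourier.
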