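# esmgre

An in-silico toolkit for **echo-shifted multi-echo gradient-echo
(ES-mGRE)** MRI: a sequence that quantifies T2\* of both brain tissue and
cerebrospinal fluid (CSF) — whose T2\* is an order of magnitude longer —
without prolonging the repetition time, and that simultaneously estimates
a 1-D diffusivity of CSF from the diffusion weighting of its echo-shifting
gradients.

The package is aimed at sequence developers and quantitative-MRI
methodologists who want to study this acquisition and its estimator
without a scanner: it simulates the sequence end to end and fits the
resulting (or user-supplied) multi-echo magnitude data.

## What it does

* **Sequence timing and gradients** — builds the per-sub-TR gradient
  waveform (bipolar readout train with navigator slots, the echo-shifting
  gradient pair with area ratio −1:+2 scaled by the knob *K*, duplicated
  spoiling lobes) on a 0.01 ms raster, verifies echo formation and
  spoiling through zeroth-moment analysis, and computes per-echo b-values
  by moment integration:
  b(TEₙ) = γ² ∫₀^TEₙ (∫₀ᵗ G dt′)² dt over the read and slice axes.
* **Digital phantom and forward model** — a five-region rectangular brain
  phantom evaluated with the spoiled-GRE steady state:
  s(TEₙ) = M₀ sin α (1−e^(−TR/T1))/(1−cos α e^(−TR/T1)) ·
  e^(−TEₙ/T2\*) · e^(i(φ₀+2πΔf·TEₙ)) · e^(−b(TEₙ)·D) + ε(0, σ²).
* **K-space and navigator correction** — per-line acquisition under
  physiological frequency fluctuations and the two-step navigator phase
  correction in hybrid (x, k_y) space, with an SNR-gated median fallback
  for low-SNR positions and a ghost-energy metric.
* **Voxelwise fitting** — maximum-likelihood estimation of M₀, T2\* and D
  under a Rician magnitude likelihood (σ from background-corner ROIs),
  s(TEₙ) = M₀ e^(−TEₙ/T2\*) e^(−b·D) e^((−1)ⁿδ), with iterative
  correction of the bipolar modulation δ and per-voxel model comparison by
  corrected AIC (cAIC).
* **Simulation grid** — the echo-count × K × shifted-count study with
  region summary statistics (means/SDs, CSF median–quartile summaries
  with inclusion filters, Kolmogorov–Smirnov comparisons).

## Worked example

```r
library(esmgre)

cfg <- es_preset("table1_invivo")   # 64 echoes, 21 shifted, K = 10
cfg
#> ES-mGRE protocol: TR 3000 ms / 23 slices (sub-TR 130.43 ms)
#>   echoes: 43 prompt + 21 shifted, TE1 3 ms, dTE 1.47 ms, K = 10
#>   flip 60 deg, matrix 240 x 216, 2 mm slice, 800 Hz/px

tr <- build_echo_train(cfg)
range(tr$te[!tr$shifted]); range(tr$te[tr$shifted])
#> [1]  3.00 66.21
#> [1] 203.69 234.56
round(range(tr$b[tr$shifted]))
#> [1] 227 227
```

The prompt echoes (3–66 ms) sample the tissue decay, the shifted echoes
(204–235 ms, read during the next slice's sub-TR interval) sample the slow
CSF decay, and the K = 10 echo-shift gradients give them a diffusion
weighting of ≈227 s/mm² while the prompt echoes stay below 0.3 s/mm².

Simulating and fitting one CSF-like voxel (T2\* 1800 ms, D 3.0 µm²/ms) at
SNR 50 with the desk-scale phantom protocol:

```r
phcfg  <- es_protocol()                       # TR 1200 ms, 64x64 matrix
train  <- build_echo_train(phcfg)
sigma  <- sigma_for_snr(phcfg, snr = 50)
csf    <- es_tissue_defaults()[5, ]
s      <- Mod(simulate_voxel_signal(csf, train, phcfg,
                                    es_noise(sigma, seed = 4)))
fit_voxel(s, train, fit_model(), sigma)
#> es_fit: M0 = 0.2967, T2* = 1724 ms, D = 3.083 um^2/ms, delta = 0
#>   logLik 207.3, k = 3, n = 64, cAIC -408.2, converged: TRUE

fit_voxel(s, train, fit_model(include_diffusion = FALSE), sigma)$T2star
#> [1] 256
```

With the diffusion term the fit recovers T2\* ≈ 1724 ms and
D ≈ 3.08 µm²/ms; omitting it misreads the diffusion attenuation of the
shifted echoes as relaxation and collapses CSF T2\* to ~256 ms — the bias
the model comparison (cAIC −408 vs −257 here) flags voxelwise. Single-voxel
CSF estimates scatter widely (the shifted block spans only ~13% of a CSF
T2\*); region statistics over many voxels are the intended readout.

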