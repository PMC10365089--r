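---
title: "Cyclic simulation and denoising for low-dose CT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic simulation and denoising for low-dose CT: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lowering the tube current-time product (mAs) of a CT acquisition lowers the
patient's radiation dose and raises quantum noise in the reconstructed image.
Supervised denoisers need paired (noisy, clean) scans of the same anatomy,
which clinical practice cannot provide: nobody scans a patient twice at two
doses. An anthropomorphic physical phantom *can* be scanned across a whole
dose ladder, yielding perfectly paired data that carries the scanner's true
noise statistics — but a phantom has no anatomical texture, and a denoiser
trained only on phantom pairs learns to flatten everything that is not an
edge, destroying tissue detail on real patients.

`csdct` implements a cyclic simulation-and-denoising (CSD) framework that
couples two generative networks to get the best of both worlds without any
patient low-dose data:

* a **noise simulator** `G_s` (u-shaped encoder-decoder with skip
  connections) that maps a clean image to a simulated low-dose image, and
* a **denoiser** `G_d` (residual plain CNN in the DnCNN family: it predicts
  the noise and subtracts it) that maps a low-dose image back to a clean one,

with a strided **patch discriminator** `D_s` estimating the probability that
a patch comes from the real low-dose distribution.

## Objectives

Write `H` for a clean (standard-dose) image, `L` for a real low-dose image,
and hats for network outputs. The additive baseline model is `L = H + N`.
The package implements four loss terms as pure functions:

* adversarial terms (classic minimax value, on discriminator probabilities):
  `E[log D(L)] + E[log(1 - D(G_s(H)))]`, once for the forward cycle (S2D)
  and once for the reverse cycle (D2S), where the D2S fake branch re-noises
  the denoiser's output: `D(G_s(G_d(L)))`;
* two l1 terms for the denoiser: `E|H - G_d(G_s(H))|` (S2D: denoise the
  simulator's output back to its clean input) and `E|H - G_d(L)|` (D2S:
  supervised regression on phantom pairs plus simulated patient pairs).

The total objective is the weighted sum
`lambda1 * gan_s2d + lambda2 * gan_d2s + lambda3 * l1_s2d + lambda4 * l1_d2s`
minimized over both generators and maximized over the discriminator.
`loss_report()` records all four terms and their weighted sum per update; the
identity is exact by construction and tested.

Two realization choices deserve explanation:

* **Generator updates are non-saturating.** The minimax form
  `min log(1 - D(G))` has vanishing gradients when the discriminator wins;
  the package maximizes `log D(G)` instead, the standard stable variant.
  Probabilities are clamped at `1e-7` inside logarithms.
* **The l1 terms train the denoiser only (`sim_feedback = "none"`).** Both
  l1 losses are written as functionals of `G_d`; the simulator learns from
  the adversarial terms, and the two networks still couple through the data
  each generates for the other (the simulator feeds the denoiser simulated
  patient pairs; the denoiser feeds the simulator its restorations to
  re-noise). We also implement the two explicit couplings — the S2D l1
  gradient flowing into `G_s` cooperatively (`"joint"`) or with reversed
  sign (`"adversarial"`, simulation that is harder to denoise) — behind the
  `sim_feedback` flag. The joint coupling is not the default because, with
  the pixel weights dominating (`lambda = (1, 1, 10, 10)`), it measurably
  collapses the simulator toward the identity: the cheapest way to make
  denoising easy is to inject no noise at all. In our desk-scale runs the
  injected-noise amplitude fell from ~50 HU to ~0.1 HU within 500 steps
  under the joint coupling, while the default keeps it near the target.

## Two-stage schedule

Stage 1 pretrains the two generators independently on the phantom ladder:
the denoiser by supervised l1 on paired crops, the simulator adversarially
against real phantom low-dose crops. Stage 2 alternates the two cycles
within every macro-step (S2D then D2S, ratio configurable), drawing clean
batches from both domains (at least one phantom and one patient image per
S2D batch) and phantom pairs plus freshly simulated patient pairs for D2S.

Training is patch-based (default 32 px crops in the tiny profile, 64 px in
the full defaults) with full-image inference; the denoiser is fully
convolutional and translation-compatible away from borders, which is tested.

Determinism: every random draw (weight init, crops, latent noise, batch
sampling) derives from the plan seed through R's RNG; a fixed seed gives
bit-identical histories and weights on one device, checkpoints capture the
RNG state, and a resumed run reproduces the uninterrupted run bit-exactly.
Cross-device bit-equality is not promised (BLAS reduction order may differ).

## Stabilizing the adversarial amplitude at desk scale

The simulator's entire job, restated statistically, is that the standard
deviation of `G_s(H) - H` should match the dose-matched noise level
`sigma(d)` — on *patient* images, although only phantom noise was ever
observed. Small GANs estimate this equilibrium noisily, and three design
choices keep the desk-scale profile honest rather than lucky:

* **Near-identity initialization.** The simulator's output head is scaled
  by 0.02 at initialization, so training grows the injected noise from ~0
  toward the real amplitude. He-initialized residual heads start at several
  hundred HU of structured perturbation, and the adversarial signal then
  has to tame a wild generator instead of calibrating a quiet one — we
  observed amplitudes stuck in the 300-600 HU range when doing that.
* **A fast discriminator.** The discriminator learns at `lr_d = 2e-3`, 20x
  the generator's `lr_g = 1e-4` (tiny profile). With the two rates equal
  the discriminator lags, its decision boundary is stale, and the
  amplitude oscillates by factors of 2-4.
* **Polyak averaging of the simulator.** During stage 2 the package keeps
  an exponential moving average (decay 0.995, a ~200-step horizon) of the
  simulator weights and uses it both for inference and for generating the
  simulated patient pairs the denoiser trains on in D2S. The raw iterate
  orbits the GAN equilibrium; its time-average sits near the center of the
  orbit.
* **A latent channel visible to the output head.** The simulator's input is
  the clean image concatenated with a unit-Gaussian channel, and that
  channel is also concatenated directly into the final convolution's
  input. Without the skip, every noise path runs through 3x3 chains and
  the injected noise is strongly low-pass; the denoiser then trains on
  spectrally wrong noise and measurably underperforms on the true white
  field at test time.
* **Best-checkpoint selection.** Stage 2 runs a fixed step budget, scores
  the denoiser on the held-out phantom split every `val_every` macro-steps,
  and inference uses the best-scoring denoiser. This guards against a real
  late-training failure mode we observed: the S2D discriminator's real
  branch contains only phantom patches, so with enough patient diversity
  the simulator is pushed to "phantomize" patient images (suppress their
  texture) rather than just add noise; the denoiser, trained in D2S to
  invert the simulator, then learns to add spurious texture and its error
  on genuinely noisy images grows by tens of HU. The phantom validation
  split catches the degradation and selection rolls inference back to a
  healthy checkpoint.

## The synthetic data generator

`generate_phantom_slice()` draws an elliptical skull ring (+1000 HU) around
a uniform soft-tissue interior (40 HU) with 3-5 uniform tissue-equivalent
inserts on an air background: piecewise-constant by construction, because
the *absence of texture* is the phantom's defining statistical property.
`generate_patient_slice()` shares the gross geometry but perturbs the head
outline with low-order harmonics, adds ventricle-like low-HU structures,
and — the load-bearing feature — correlated intra-tissue texture: a
Gaussian random field smoothed to a correlation length of 2-8 px and scaled
to 5-15 HU, the amplitude range of genuine soft-tissue contrast. The median
local standard deviation inside soft tissue separates the two domains with
zero overlap across seeds, which is the premise behind the phantom-only
failure mode the comparison harness reproduces.

The noise model is the image-domain excess-variance quantum-noise law
`sigma(d) = k * sqrt(max(0, 1/d - 1/d_ref))` with `d_ref = 175` mAs treated
as exactly clean and `k = 190` HU·sqrt(mAs), putting the 20 mAs
ultra-low-dose level at ~40 HU. The dose ladder spans 5-95 mAs in 5 mAs
steps; training uses the 20/30/60 mAs levels by default. Noise is additive
Gaussian in HU applied to reconstructed slices; what the generator does
*not* emulate — correlated streak noise, beam hardening, scatter,
reconstruction-kernel effects, real anatomy — bounds what passing tests
show: they validate the framework's mechanics and its directional claims
in an additive-Gaussian world, not clinical performance.

## Numerical choices

* HU is the only internal pixel unit; networks see an affine map of the
  window `[-1024, 1024]` onto `[-1, 1]` (no clipping), inverted at output.
* PSNR uses an explicit `data_range` (default 2048, the normalization
  window width) and returns an `Inf` sentinel at zero MSE; SSIM uses the
  canonical 11x11 Gaussian window, sigma 1.5, `k1 = 0.01`, `k2 = 0.03`,
  population covariance, symmetric boundary, borders cropped — verified
  against an independent reference implementation at 1e-6.
* Adam (beta 0.9/0.999, eps 1e-8) everywhere; l1 subgradient `sign(x) = 0`
  at exact zero; probability clamping 1e-7; all seeds derived from one
  master seed and kept within 32-bit integer range.
* Tiny-profile sizes were chosen once for single-CPU runs of minutes:
  simulator 2 levels x 8 channels, denoiser 5 layers x 8 channels,
  discriminator 3 layers x 8 channels, 32 px patches, batch 4; the test
  suite trains at 300-500 pretraining steps, 300-500 cyclic macro-steps,
  and the comparison experiment at 600 macro-steps on 6 phantom and 12
  patient slices of 64 px. Full-size profiles (e.g. DnCNN-scale depth 17)
  are plain configuration changes.

## Known limitations

* The adversarial amplitude match is statistical, not exact: across seeds
  the recovered noise level scatters around the target by roughly 10-25%
  at desk scale. The acceptance checks therefore test majorities over
  seeds, not single runs.
* One discriminator is shared by both cycles (the symbol `D_s` is one
  network throughout); a separate-discriminator mode is deliberately out
  of scope.
* The simulator conditions on dose implicitly through its training data:
  one trained simulator represents the dose mixture it saw, not an
  explicit dose dial.
* Phantom-vs-patient discrimination leaks through the discriminator (its
  real low-dose patches are phantom-only). At desk scale this appears as
  amplitude drift and, with many patient slices, as the texture-suppression
  failure mode described above; Polyak averaging and best-checkpoint
  selection contain it rather than remove it.
* In this synthetic world the low-dose noise is exactly the additive
  Gaussian field the phantom pairs carry, so a plain phantom-trained
  denoiser is a near-oracle baseline; the cyclic framework's margin over
  it is small in PSNR (its structural-similarity margin is consistent),
  and the directional comparison is therefore checked as a majority over
  seeds. With real scanner noise the phantom-only baseline's handicap —
  never seeing tissue texture under the *actual* noise process — is the
  gap the framework exists to close.
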