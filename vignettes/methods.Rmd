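---
title: "Sonifying brain slices and fusing image and audio streams: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sonifying brain slices and fusing image and audio streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrisonify)
```

This vignette is the package's own account of the science it implements: the
image-to-audio transform, the two classification streams and their fusion,
the parameters that matter, and the choices made where the method left the
design open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The sonification model

A grayscale 2D brain slice $I(x,y)$, min–max normalized to $[0,1]$, is
converted into a 16 kHz waveform in five steps.

**Gabor texture energies.** The slice is convolved with a bank of complex
Gabor kernels

$$g(x,y;f_\sigma,\theta_k) \;=\; \frac{f_\sigma^2}{\pi\gamma\eta}
  \exp\!\big(-f_\sigma^2(x'^2/\gamma^2 + y'^2/\eta^2)\big)\,
  \exp(2\pi i f_\sigma x'),$$

with rotated coordinates $x' = x\cos\theta_k + y\sin\theta_k$,
$y' = -x\sin\theta_k + y\cos\theta_k$. Four spatial frequencies and six
orientations $\theta_k = \pi k/6$ give 24 channels; the magnitude of each
complex response is the per-pixel *energy map* $E_{\sigma,k}(x,y)$. A Gabor
magnitude response is identical at $\theta$ and $\theta+\pi$ (conjugate
carrier), so orientations cover $[0,\pi)$ only — the tests verify this
tap-by-tap.

**Hilbert time mapping.** Each energy map is read out along a Hilbert
space-filling curve on the smallest $2^k \times 2^k$ grid enclosing the
image, keeping only in-bounds cells (exactly $H\cdot W$ of them, in curve
order). The retained path is cut into $T = \lceil T_{sec}\,SR/h\rceil$
contiguous, near-equal segments and each channel is averaged per segment:

$$e_t^{\sigma,k} = \frac{1}{|H_t|}\sum_{(x,y)\in H_t} E_{\sigma,k}(x,y),$$

a weighted-mean identity the tests check to $10^{-10}$ (the
frame-size-weighted sum of frame means equals the pixel sum).

**Frequency assignment and composite spectrogram.** The 24 channel series
are placed at geometrically spaced centre frequencies from 220 Hz to
3000 Hz, snapped to the nearest STFT bin, *added* into the magnitude array
(bin collisions superpose; with the default 1024-point FFT at 16 kHz the 24
bins are distinct), and max-normalized to $[0,1]$.

**Phase reconstruction.** Griffin–Lim inverts the magnitude spectrogram:
starting from seeded uniform random phase, it alternates ISTFT and STFT,
keeping the analysed phase and re-imposing the target magnitude. Sixty
iterations reduce the spectral-convergence error of a 440 Hz test tone to
roughly a third of its 1-iteration value (the acceptance script recomputes
both numbers). The waveform is peak-normalized to 0.95 and trimmed to the
nominal duration.

### Why the Hilbert curve, mechanistically

Each spectrogram time frame summarizes one path segment. Hilbert segments
are compact blobs (`segment_compactness()`: RMS radius ≈ 9 px for 150×150
images at the default 64 frames), while raster segments are 2–3 full rows
(≈ 43 px): a raster frame mixes anatomy from opposite ends of the slice, a
Hilbert frame does not. We also report a neighbour-index locality score —
the **median** |1-D index difference| over all 4-neighbour pixel pairs,
which is exactly 1 for Hilbert (more than half of all neighbour pairs are
consecutive on the curve) versus $(1+W)/2$ for raster. The *mean* of the
same quantity is deliberately not the default summary: it is dominated by
the rare pairs that straddle quadrant seams of the recursive construction
and can rank raster ahead of Hilbert even though raster segments are far
more dispersed; `locality_score(..., summary = "mean")` remains available
for that comparison.

### Free parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| Gabor frequencies $f_\sigma$ | 1/32, 1/16, 1/8, 1/4 | cycles/pixel | octave ladder up to half-Nyquist; ascending so scale-major channel order puts coarse structure at low audio frequencies |
| $\gamma, \eta$ | 1, 1 | — | isotropic envelope; nothing in the method fixes them |
| kernel truncation | 3 envelope SD, odd side | pixels | <1e-4 tail truncation; reflect padding avoids edge ringing |
| duration $T_{sec}$ | 2.0 | s | enough for 64 frames at hop 500; not fixed by the method |
| sample rate | 16000 | Hz | the method's stated output rate |
| hop $h$ | 500 | samples | 32 frames/s; not stated by the method |
| band | 220–3000 | Hz | stated; the upper edge is read as Hz since 3000 kHz would exceed Nyquist |
| $n_{fft}$ | 1024 | samples | 15.6 Hz bins resolve all 24 geometric centres to distinct bins |
| Griffin–Lim iterations | 60 | — | convergence has plateaued on the test tone |
| peak target | 0.95 | — | headroom against 16-bit PCM clipping |

Normalization of the composite spectrogram is **global** max-normalization
(the per-frame variant exists behind `normalize = "frame"`): the two
readings of the procedure disagree, and the global form keeps relative
frame energies — the information the traversal was designed to preserve.

## 2. The image stream

The image classifier is a deliberately small attention-fusion network
(9,903,677 trainable parameters, accounted layer-by-layer by
`count_parameters()` and asserted exactly in the tests): three depthwise
separable convolution blocks (3×3 kernels; 32, 64, 128 filters; ReLU; 2×2
max-pool with floor division, so 150 → 75 → 37 → 18), a branch per block
(flatten → dense 32 → layer normalization), a shared dense(32, ReLU) and
shared dense(1) over the stacked branches giving three logits, softmax
attention weights, an attention-weighted sum of the *stacked branch
vectors*, and a sigmoid output unit. Grayscale slices are replicated to
three channels to match the 150×150×3 input.

No deep-learning runtime is involved: forward, backward and the Adam update
are implemented in single-precision C++ (RcppArmadillo), with gradients
verified against central finite differences in the test suite. Training
follows the study settings — Adam, learning rate $10^{-4}$, 20 epochs,
binary cross-entropy, batch size 32 — and is bit-reproducible for a fixed
seed: initialization (Glorot uniform) and shuffling derive from R's seeded
RNG, and the single-threaded C++ core is deterministic. Layer
normalization uses $\varepsilon = 10^{-5}$ over the 32-feature axis with
learned gain and bias (64 parameters per branch). 'Same' spatial padding
and floor pooling are forced by the published shape ladder. No data
augmentation is applied.

## 3. The audio stream

Sonified waveforms pass through a *frozen* embedder and a 100-tree random
forest emitting class probabilities. The pretrained 1024-dimensional audio
network used in the original study cannot be bundled or downloaded offline,
so the default embedder is the package's log-mel filterbank-statistics
embedder: 0.96 s windows with 0.48 s hop, 32 triangular mel bands on a
1024-point STFT, and per-band mean and standard deviation over time — a
64-dimensional frame embedding. A `pretrained_audio_embedder()` adapter
(reporting `dim = 1024`) accepts a user-supplied backend; swapping
embedders changes numbers but no pipeline contract, which the tests assert.
Frame embeddings are mean-pooled by default; `"flatten"` (the
fixed-duration reading) is available because all sonified audio in a run
shares one duration.

## 4. Fusion by stacked generalization

Each stream is trained inside a stratified 5-fold cross-validation; a
sample's stream probabilities always come from models whose training folds
excluded it (out-of-fold, OOF). The stacked pairs
$z_i = (\hat p_i^{img}, \hat p_i^{aud})$ feed a logistic meta-classifier
$p^{fus} = \sigma(w^\top z + b)$, fitted with a very weak ridge penalty
($\lambda = 10^{-4}$, effectively maximum likelihood but finite under
perfect separation; a two-parameter model cannot meaningfully overfit).
Deployment models are refitted on all training data after stacking.

Reported *fused* performance is itself cross-fitted: the meta-classifier
scored on fold $k$ was fitted on the other folds' stacked pairs
(`crossfit_fusion()`). Scoring the deployment meta-classifier on its own
training pairs is optimistic, and with grouped subjects the effective
sample count is the subject count, so that optimism is visible at chance
level (a null run scores noticeably above AUC 0.5). Cross-fitting restores
an unbiased chance-level null while leaving the deployment model exactly as
specified. When
subject identifiers exist, folds are grouped so no subject spans folds —
slices of one scan are strongly correlated, and the grouped plan is the
default whenever `subject_id` is present. The decision threshold for
tabled metrics is 0.5; metrics with empty denominators are reported as
`NaN` with a flag rather than silently zeroed.

The no-leakage property is mechanically tested: a trainer that *memorizes*
its training labels, evaluated OOF on label-permuted data, scores AUC 0.5
exactly (every OOF prediction falls back to the unseen-input value) — if
OOF bookkeeping ever leaked a fold, this canary would score near 1.

## 5. The phantom generator

Real T1-weighted cohorts are access-controlled, so the package generates
two-class brain phantoms: an elliptical soft-edged "brain" containing a
central dark "ventricle" and band-limited interior texture (a superposition
of eight random-phase plane waves around a class-dependent frequency), plus
additive Gaussian noise, clipped to $[0,1]$. The two class axes mirror the
two discriminative mechanisms the method claims: texture frequency
(0.07 vs 0.13 cycles/pixel at full effect — Gabor-visible) and ventricle
radius ratio (0.16 vs 0.30 of the brain radius — structure the traversal
turns into slow audio envelopes; enlarged ventricles accompany atrophy in
the diseased class). The effect size $\delta \in [0,1]$ interpolates the
class-1 parameters; $\delta = 0$ makes the class distributions identical by
construction. Nine slices per synthetic subject share subject-level
parameter jitter, mirroring per-scan slice sets; slices carry segment
labels 4–12. Phantoms default to 150×150 so no resizing sits between
generator and classifier.

What the phantoms do *not* emulate: MRI physics (bias fields, partial
volume, acquisition noise spectra), skull or non-brain tissue, realistic
anatomy, or registration error. Passing the end-to-end tests therefore
shows that the pipeline recovers the two planted effect axes under
controlled conditions — not that it attains any particular accuracy on
clinical data.

A simplified entropy-based slice ranking (`select_slices_by_entropy()`,
Shannon entropy of the 256-bin masked intensity histogram, ties to the
lower index) stands in for the original study's feature-entropy slice
selection, whose exact criterion is defined outside the source available
here; it is labelled as a stand-in in its documentation.

## 6. Problem sizes, determinism and numerical choices

The stochastic end-to-end checks run at $n = 200$ slices (100 per class,
~12 subjects per class) with the full default pipeline — these are the
package's chosen study conditions for desk-scale verification. The
separable condition ($\delta = 1$) is run once per suite execution; the
null condition ($\delta = 0$) is run twice with distinct seed-derived
substreams and the out-of-fold predictions pooled before computing the null
AUC, because the subject-grouped design leaves only ~22 effective samples
per run and the chance band needs the tighter pooled estimate (a four-run
full-scale calibration of the cross-fitted null informed this replication
choice). The "stacking rarely hurts" property is additionally exercised
over 20 seeded replicates with inexpensive surrogate stream trainers in the
fusion unit tests, and the monotonic-difficulty property of the generator's
separation knob over effect sizes $\{0, 0.5, 1\}$ runs through the
sonification/audio path at miniature scale (80×80 slices, one slice per
subject, 3-scale bank) — full-pipeline replication at every effect size
would be disproportionate to what it buys. Unit tests of the streams use
80×80 phantoms and a 3-scale bank (the coarsest default kernel, radius
68 px, does not fit a 64×64 image — undersized inputs raise an error naming
the minimum size).

All randomness flows from one global seed through named substreams
(`substream_seed(seed, name)`): Griffin–Lim phase, CNN init/shuffle, forest
bootstrap, fold shuffling, phantom generation. The Gabor stage is
deterministic. Reruns with the same config and seed produce byte-identical
metrics files.

Numerical details: FFT convolution operates on a reflect-padded canvas
(mirror without edge repetition) large enough that circular wrap-around
never reaches the retained centre, and matches the direct sliding-window
reference to ~1e-15 relative; kernel spectra are cached per image size.
The CNN runs in float32 — gradient checks use central differences with
tolerances set by float arithmetic, and batched and one-by-one prediction
agree within 1e-6 (an exactness test would be wrong in float). Max-pool
ties resolve to the first maximum in column-major order; Hilbert
generation is iterative bit manipulation (orders ≤ 15, well past any
realistic slice size).

## 7. Known limitations

- The fallback audio embedder is not the pretrained network of the original
  study; absolute audio-stream numbers are not comparable to published
  accuracies, only the pipeline contracts and relative behaviour are.
- 2D slices only; no 3D traversal or volumetric sonification.
- With nine correlated slices per subject and grouped folds, the effective
  sample size of an out-of-fold AUC is the subject count (~22 at n = 200),
  so null-condition estimates carry subject-level variance; held-out
  evaluation on fresh data is available through `run_pipeline()` /
  `evaluate_pipeline()`.
- Phantom realism as described above; no claim transfers to clinical MRI
  without real data.
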