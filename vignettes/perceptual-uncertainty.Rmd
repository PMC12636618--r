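---
title: "Stimulus-computable perceptual uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-computable perceptual uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(percept)
```

## The problem

When a listener reports where a sound came from, or which of two tones was
higher, the judgment comes with a sense of confidence. A long-standing
hypothesis holds that confidence reflects an internal estimate of the
reliability of the decision — that perception computes not just a point
estimate of a variable but a distribution over it. `percept` implements a
framework for building such stimulus-computable uncertainty representations:
a neural-network readout maps an auditory stimulus to the parameters of a
mixture distribution over the task variable, is trained by maximum
likelihood, and the resulting posterior is summarized into decisions and
graded confidence judgments that can be compared with post-decision wagers.

Two perceptual domains are covered. For sound localization the readout is a
mixture of `K = 5` factorized bivariate von Mises components over azimuth
and elevation — circular distributions, so no boundary artifacts arise at
±180°, and multimodality (e.g., front/back image pairs on the cone of
confusion) is representable. For pitch the readout is a univariate Gaussian
mixture over `s = log f0` (natural-log Hz), whose multimodality captures
octave ambiguity.

## Why maximum likelihood

The univariate case makes the logic visible. The negative log-likelihood of
a label $y$ under a predicted Gaussian,

$$\mathcal{L} = \tfrac{1}{2}\log 2\pi + \tfrac{1}{2}\log\sigma^2(x) +
\frac{(y-\mu(x))^2}{2\sigma^2(x)},$$

reduces to mean squared error when $\sigma^2$ is constant, but when
$\sigma^2$ is predicted from the input the two terms trade off: shrinking
the variance pays only when the squared error is small, so the minimizer
predicts narrow distributions exactly where the stimulus supports accurate
estimation. The NLL is a strictly proper scoring rule, so calibrated spread
is optimal, not incidental. A classifier trained with cross-entropy has no
such pressure — only the true class enters the loss — and its softmax
distribution is systematically overconfident. `run_calibration_demo()`
reproduces both facts on a synthetic task (below).

## Readout parameterization

All constraint transforms follow the same scheme:

* **weights** — softmax to the simplex (`constrain_weights()`);
* **circular means** — raw pairs $(u, v)$ squashed by `tanh` and mapped by
  `atan2(tanh u, tanh v)` to $(-\pi, \pi]$ (`constrain_circular_mean()`);
  the degenerate all-zero case returns 0 with a warning;
* **concentrations** — a bounded rectifier (`relux(x, 1, 512)`). The lower
  bound keeps components from collapsing to the uniform circle during
  optimization; the upper bound of 512 corresponds to a wrapped normal with
  variance $\approx 1/512 \approx 0.002\,\mathrm{rad}^2$, effectively a
  delta function at 1° resolution, and prevents numerical blow-up;
* **log-f0 means** — `relux(x, 3, 10)`; $e^3 \approx 20$ Hz and
  $e^{10} \approx 22$ kHz bracket the audible range (the bounds only make
  sense on a natural-log axis);
* **variances** — `softplus(v) + 1e-9`, strictly positive.

The von Mises normalizer uses a piecewise polynomial `log I0` with the
textbook coefficient sets and a switch at exactly 3.75: the small-argument
polynomial is logged directly, the large-argument asymptotic form is
evaluated in log space (`log I0(k) ≈ k − ½ log k + log P(3.75/k)`), so the
loss is finite and differentiable up to the concentration cap. The
gradient of the normalizer, `I1/I0`, is computed from the companion `log I1`
polynomials. Tests pin both against a converged power-series oracle to
1e-4 absolute over the full [0, 512] range.

## Training

`train_mdn()` is a hand-written minibatch Adam loop with analytic
backpropagation through the mixture NLL and every constraint transform
(gradients are verified against finite differences in the test suite). The
learning-rate schedule is linear warmup → plateau → multiplicative decay;
defaults follow the two task recipes (localization: lr 0.001, 20% warmup,
20% decay at γ = 0.9 per decay step, batch 64; pitch: 10% warmup, γ = 0.99,
batch 128). "Per decay step" is our reading of the multiplicative factor —
the interval is not stated — and simply anneals the rate toward zero over
the final phase. Early stopping triggers when the epoch-mean loss improves
by less than 1e-4 relative for one epoch (patience 1), and a non-finite
loss aborts with the last finite checkpoint. All randomness (data order,
initialization, augmentation) flows from a single integer seed;
`derive_seed()` gives independent substreams per pipeline stage.

No automatic-differentiation framework is involved by design: the readout,
objective, and constraint chain *are* the contribution here, and writing
their gradients explicitly keeps the package dependency-free and the
mathematics inspectable.

### The backbone

The full-scale models behind this framework use deep convolutional
backbones trained on tens of millions of rendered scenes. At desk scale we
replace the learned convolutional stack with a fixed binaural cue-extraction
stage plus a small fully-connected network: for each cochlear channel, mean
log energy, interaural level difference, interaural cross-correlation lag
(±1 ms) and its peak value (`binaural_features()`), standardized and fed to
two rectified hidden layers (64, 48). This is a stand-in, not a
reproduction: it hard-codes the cues a convolutional front end would have
to discover, which is precisely what makes minutes-scale CPU training
feasible.

## The periphery

`cochleagram()` implements the filterbank front end: ERB-spaced gammatone
FIR kernels (4th order, `b = 1.019·ERB(cf)`, peak-gain normalized at cf),
half-wave rectification, 0.3 power-law compression, lowpass filtering and
downsampling with a Kaiser-windowed sinc resampler (width 64, rolloff
0.94759, β = 14.76965), and a center crop. Two presets match the published
pipelines exactly in shape: binaural localization (40 channels, 40 Hz–20 kHz,
25 ms kernels at 48 kHz, ~3.79 kHz lowpass — the anti-alias cutoff of the
8 kHz resampler at the configured rolloff — cropped to 1 s: `2 × 40 × 8000`)
and monaural pitch (100 channels, 60 Hz–16 kHz, 3 kHz lowpass, 20 kHz output,
50 ms crop: `100 × 1000`). The two presets apply compression and lowpass in
different orders, as their sources do; both orders are supported via
`stage_order`. Choices the sources leave open: the pitch-preset FIR
truncation is 50 ms (a 60 Hz channel needs longer support than 25 ms), and
the pitch preset's native input rate is 40 kHz (divides evenly into the
20 kHz output rate while keeping Nyquist above the top CF). A reduced
`"toy_binaural"` preset (24 channels, 150 Hz–7 kHz, 16 kHz, 200 ms crop, no
downsampling so fine timing survives for the cross-correlation features)
serves the desk-scale studies.

## From posterior to behavior

* `map_estimate()` draws 5000 samples, bins the azimuth and elevation
  marginals at 1° and returns the modal bin centers. Marginal histograms
  are used instead of a joint 2-d histogram because 5000 samples cannot
  populate a 360×360 grid and every decision studied here is azimuthal or
  hemifield-based; ties break toward the midline, then the lowest index.
* `hpd_width()` scans all contiguous circular windows for the shortest arc
  holding 50% of the histogram mass — the uncertainty measure for absolute
  localization (a uniform posterior gives 180°).
* `front_back_entropy()` integrates the azimuthal posterior over the front
  hemifield (|az| ≤ 90°, the boundary assigned to "front"; the protocols
  omit 90° so the convention is inconsequential but fixed) and returns the
  binary entropy in bits — the confidence measure for front/back judgments.
  Bits rather than nats is arbitrary: any base gives the same bet ordering
  under the monotone mapping below.
* `constrained_map_f0()` restricts the pitch MAP to ±1 octave around the
  trial's nominal f0 (listeners expect the two tones of a trial to be
  close), with 1/16-semitone bins and a half-open upper edge; if no sample
  lands in the window the density is evaluated on a grid instead.
* `mode_local_variance()` measures the width of the dominant posterior mode:
  the variance of the density renormalized within one octave of the mode,
  by dense grid quadrature (grid resolution adapts to the narrowest
  component).
* `assign_bets()` converts pooled uncertainties to 1–5 wagers by inverse
  CDF: sort descending, then cut at the cumulative probabilities of a
  discrete Gaussian prior over bets (`exp(−(k−3)²/2)`, normalized). Block
  sizes come from largest-remainder rounding so they sum to N exactly; ties
  keep original trial order. One mapping is computed per experiment.

## The synthetic scene generator

Stimuli (tones, one-octave narrowband noise, broadband noise with
randomized 20–60 Hz / 8–16 kHz edges, harmonic complexes, trapezoidal
spectral filtering at 50 dB/octave, threshold-equalizing noise shaped to
constant power per ERB) follow the published experimental parameters; every
generator is a pure function of its arguments and seed.

`toy_spatialize()` replaces the out-of-scope room/HRTF renderer with
schematic, lawful cues: a Woodworth ITD `τ = (r/c)(λ + sin λ)` on the
lateral angle λ (so front/back pairs share interaural cues, preserving the
cone-of-confusion structure), a frequency-dependent ILD growing to ~12 dB,
an elevation-dependent spectral notch (4.2–5.4 kHz band), a broad −12 dB
rear shelf above 3 kHz as the spectral front/back cue, and a −3 dB rear
direct-to-ambient penalty standing in for head/torso shadowing. The notch
and shelf occupy separable bands on purpose — a narrowband dip and a broad
tilt are distinguishable to the readout, as pinna and shadow cues are in
real ears. Training scenes place a target at a 10°-grid azimuth (full
circle) and 0–40° elevation over diffuse uncorrelated background noise at
an SNR drawn uniformly from [−15, 30] dB, RMS-normalized to 0.1.

What this emulates — and what it does not. The generator reproduces the
*cue structure* of spatial hearing (lateral cues, spectral elevation and
front/back cues, their stimulus-bandwidth dependence and their ambiguity
for narrowband sources). It does not contain reverberation, measured HRTFs,
source spectra of natural sounds, or realistic cue noise. Passing the
desk-scale studies therefore shows that the *machinery* — readout, loss,
posterior summaries, wager mapping — behaves as designed when the cues are
lawful; it does not certify quantitative agreement with human hearing.

## Desk-scale studies and what they show

`run_calibration_demo()` (the package's central calibration check) trains
the Gaussian-mixture readout on a task where the label noise is a known
function of the input (σ spans 0.05–0.5 across inputs), with 20,000
training and 5,000 held-out examples. The trained readout's predicted
spread correlates with the true σ at r ≈ 0.98, and its 50% HPD intervals
cover the truth on ≈ 49% of held-out trials. The categorical cross-entropy
baseline trained on the same task (64 bins, softmax-entropy confidence)
correlates with true σ at only r ≈ 0.5 — the overconfidence contrast.

`train_toy_localizer()` (3000 scenes, ~3 minutes CPU) plus `run_exp3()`
(7 conditions × 19 azimuths × 3 repeats = 399 trials) and `run_exp4()`
(4 conditions × 18 azimuths × 5 elevations = 360 trials) reproduce,
direction-only: mean 50% HPD width orders broadband < narrowband < pure
tone; front/back d′ is high for broadband noise (≈ 3–4) and near chance
for tones, with the entropy confidence correspondingly ordered. One
documented deviation: pooled HPD width *decreases* from midline to ±80°
here, opposite the full-scale finding. In a free-field cue world the
front/back images of a tonal source are 180° apart at the midline and merge
near ±90°, so the contiguous 50% HPD arc is forced wide exactly at the
midline; the full model's room reverberation and measured pinna cues tilt
enough mass to the correct hemifield for the cue-slope trend (blur growing
with eccentricity) to dominate instead. Strengthening the toy rear cue far
enough to flip the trend destroys the bandwidth ordering first, so we
report the deviation rather than distort the generator.

Problem sizes throughout (3000 training scenes, 24-channel toy periphery,
5000-sample posteriors, 1024 bootstrap draws) were chosen once as the
desk-scale study conditions and are stated where used.

## Numerical choices and degenerate inputs

* Histogram mode ties: toward the midline, then lowest index.
* `atan2(0, 0)`: defined as 0, with a warning.
* Largest-remainder ties in bet counts: toward the lower bet.
* Psychometric fits: least squares of `0.5 + 0.5·Φ((log Δ − m)/s)` on the
  mean psychometric function (the 0.707 criterion presupposes the 0.5–1
  range of 2AFC); thresholds capped at 100%; flat-at-chance data are
  flagged `degenerate` (threshold 100), at-ceiling data `ceiling`.
* d′ rates are clipped to `[1/(2n), 1 − 1/(2n)]` per class, so perfect
  performance yields a finite value.
* Split halves: alternating trial parity within condition — deterministic
  and balanced.
* WAV I/O, YAML configs, JSON mixture serialization and CSV trial tables
  are the interchange formats; larger objects (cochleagrams, checkpoints)
  use native R serialization.

## Known limitations

Single-source scenes only; no second-order (evidential) uncertainty; the
factorized von Mises form has no azimuth–elevation correlation terms; the
backbone is a cue-level stand-in, so absolute accuracies are not comparable
to the full-scale models; pitch experiments are exercised primarily through
stub readouts (a trained pitch model at desk scale would need a natural-
sound corpus that is out of scope).
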