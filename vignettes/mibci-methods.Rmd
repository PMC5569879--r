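---
title: "Decoding four motor-imagery states: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding four motor-imagery states: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

`mibci` implements a complete decoding pipeline for four-state motor
imagery (MI): imagined left-hand (LH), right-foot (RF) and
right-shoulder (RS) movement plus rest (R), recorded with 14 EEG
electrodes and one vertical electrooculogram (VEOG) channel at 256 Hz.
This vignette explains each stage's model, its assumptions, the
parameters that matter, and the choices made where the design was
genuinely open.

## Recording model and montage

The montage has six symmetric electrode pairs over sensorimotor and
parietal cortex (T7/T8, P3/P4, P7/P8, CP3/CP4, FC3/FC4, C3/C4), two
midline electrodes (FZ, CZ) and a bipolar VEOG derivation. Trials last
9 s: a fixation cross at t = 0 s, the task prompt at t = 2 s, imagery
until the cross disappears at t = 7 s. The analysis window defaults to
the imagery period [2, 7) s (1280 samples at 256 Hz); the window is
half-open with 0-based sample semantics, so the onset sample is included
and the end sample excluded. Each subject contributes 60 trials per
state, split 50 train / 10 test.

## Temporal filtering

A 50 Hz second-order IIR notch (quality factor 30) removes power-line
interference, and a Butterworth band-pass of order 4 isolates 8–30 Hz,
the mu/beta band that carries event-related
desynchronization/synchronization. Both filters run forward and
backward by default (zero phase), because phase distortion would smear
the imagery-locked dynamics across the trial. The zero-phase pass uses
odd-reflection padding of 128 samples (0.5 s at 256 Hz, several times
the longest filter transient) to suppress edge effects; filtering
precedes cropping to the analysis window for the same reason. The order
and the zero-phase convention are our choices — standard MI-BCI
practice — since only the filter family and band are inherent to the
method.

## Ocular artifact removal (wCCA)

Blinks project a large, frontally-weighted potential onto the EEG.
Because volume conduction spreads the artifact almost symmetrically over
both hemispheres while genuine sensorimotor activity is far less
mirror-correlated, the artifact can be isolated as the *most shared*
component of the two hemispheres. For each trial, two blocks are formed:

- `X` = the six left-hemisphere channels plus the VEOG trace,
- `Y` = the six right-hemisphere channels plus the VEOG trace.

After row-centring, canonical correlation analysis (CCA) finds
directions `a_i`, `b_i` maximizing the correlation of `u_i = a_i' X`
and `v_i = b_i' Y` under unit-variance constraints
(`a_i' Cxx a_i = 1`). Appending VEOG to *both* blocks anchors the
first canonical pair: a perfectly shared row exists, so `u1` and `v1`
lock onto the ocular component (sample canonical correlation
essentially 1). Our solver whitens each block with the symmetric
inverse square root of its covariance and takes the SVD of the whitened
cross-covariance; the sign indeterminacy is resolved by making each
left variate's covariance with its block's first channel non-negative,
flipping the paired right direction with it so correlations stay
non-negative. Covariances use the 1/(T−1) convention throughout.

Only `u1` and `v1` are denoised; `u2..u7, v2..v7` pass through
untouched. Denoising is wavelet thresholding: a 5-level db4
decomposition, the VisuShrink threshold per subband
`k_j = sqrt(2 ln N_j) * median(|D_j|) / 0.6745`, and a *suppress-above*
rule that zeroes coefficients **above** the threshold and keeps the
rest. This is deliberately the inverse of classic hard thresholding:
the large coefficients are the blink transients, the small ones the
residual EEG riding on the shared component. The approximation band is
thresholded too, because a blink is predominantly a low-frequency
event. The blocks are then rebuilt through the inverse of the canonical
basis (`X_new = (A')^{-1} U_new`), the row means are restored, and the
twelve symmetric channels are replaced; the reconstruction is exact to
numerical precision when thresholding is disabled, which is asserted in
the tests. The VEOG rows of the reconstructed blocks are discarded.

Two conventions in the threshold needed a decision. First, the robust
scale estimate uses the median of *absolute* coefficients (the standard
Donoho-Johnstone estimator); a literal signed-median mode exists behind
`mad_absolute = FALSE` because a signed reading is also defensible, but
it can produce negative thresholds on skewed subbands. Second, the
suppress-above direction is the default for the wCCA path, with
`classic_hard` available by configuration.

The midline channels FZ and CZ have no mirror partner, so they are
denoised channel-wise with *soft* VisuShrink thresholding instead. Here
the scope is restricted to the detail subbands: soft-shrinking the
approximation — which carries the bulk of any band-limited signal —
with a median-based scale estimate would annihilate a clean dense
oscillation, whereas classic denoising practice leaves the
approximation untouched. The wCCA path keeps the all-subbands scope;
the two paths target different artifacts.

## R-CSP feature extraction with generic learning

Common spatial patterns (CSP) finds, for a pair of classes, spatial
filters maximizing the ratio of projected variances. Each trial `E`
(N × T) contributes a trace-normalized covariance
`S = E E' / tr(E E')`. With few training trials the per-class average
covariance is noisy, so two shrinkage parameters regularize it:

- `beta` in [0, 1] blends the subject's own covariance *sum* `S_c`
  (M trials) with a generic sum pooled from the other subjects'
  training trials (`M_hat = M (L − 1)` trials for L subjects):
  `Sigma_c(beta) = ((1−beta) S_c + beta S_hat_c) /
  ((1−beta) M + beta M_hat)`.
- `gamma` in [0, 1] shrinks toward a scaled identity, preserving the
  trace: `Sigma_c(beta, gamma) = (1−gamma) Sigma_c(beta) +
  (gamma/N) tr(Sigma_c(beta)) I`.

(The identity matrix here is N × N — the channel dimension — which is
the only dimensionally consistent reading.) `beta = gamma = 0` recovers
classical CSP, which the tests verify against a direct
generalized-eigenproblem solver. Pooling always happens on covariance
sums, never on concatenated raw signals.

For each class pair the composite covariance is eigendecomposed
(eigenvalues descending), whitened with `P = Lambda^{-1/2} U'`, the
whitened first-class covariance is eigendecomposed again (descending,
yielding complementarity `Lambda_1 + Lambda_2 = I`), and the full
projection `W0 = B' P` is truncated to its first and last `alpha = 2`
filters — the directions where the two classes' variance ratio is most
extreme. Eigenvector signs are fixed by making each vector's
largest-magnitude entry positive, so filter banks are deterministic.
When the whitened eigenvalues tie (identical class covariances) the
descending sort with stable index tie-break still defines a unique
output. The four-class problem becomes six one-vs-one filter pairs in
the fixed canonical order (R,RF), (R,LH), (R,RS), (RF,LH), (RF,RS),
(LH,RS), and a trial's feature vector concatenates, per filter, the
log of each projected row's variance normalized by the filter's summed
variance: `6 × 2 alpha = 24` values whose per-block exponentials sum
to 1.

The `(beta, gamma)` selection grid spans [0, 1] × [0, 1] at step 0.1
(121 cells). Selecting on the test split would leak information, so the
default objective is stratified 5-fold cross-validation within the
subject's own training split (the generic pool is fixed); a holdout
mode that scores cells on a supplied test split exists for
comparability with protocols that select that way. Ties prefer smaller
`beta`, then smaller `gamma` — the least-regularized model among
equals. Grid cells reuse per-class covariance summaries and per-trial
feature covariances (`var(w'E) = w' C w` with `C` the centred trial
covariance), which makes the 121 cells cheap.

## Hybrid KNN-SVM classification

Feature clouds of overlapping MI classes cross near their boundaries;
a nearest-neighbour rule handles overlap well locally but generalizes
poorly, while a margin classifier generalizes well but is binary by
nature. The hybrid uses both: cosine-distance K-nearest neighbours
(K = 5 by default; K is a free parameter here) shortlist the two
classes with the largest neighbourhood weights; if the neighbourhood is
unanimous the class is decided directly, otherwise the one-against-one
SVM trained on exactly those two classes' training trials makes the
final call. The per-class weight is the sum of the neighbours' cosine
similarities (clamped at zero); a count-based mode exists because the
weight formula is a design choice, not part of the model. All
tie-breaks (equal weights, equal SVM votes) resolve by the canonical
class order (R, RF, LH, RS). Features are standardized per dimension
with training-split statistics before both stages; the pairwise SVMs
default to a radial basis kernel with unit cost. KNN-only and SVM-only
predictions are available from the same fitted model for classifier
comparisons.

## Synthetic data generator

No recordings ship with the package; the generator produces data with
exactly the structure the pipeline assumes, so every stage is testable
end to end:

- background 1/f ("pink") noise per channel (default sd 15 µV, with a
  1 Hz spectral floor);
- class-specific oscillations: amplitude-modulated 10 Hz and 22 Hz
  sinusoids with random phases, confined to the [2, 7) s imagery window
  under a Hann envelope, on class-specific channel groups chosen to
  follow sensorimotor physiology (LH → right hemisphere C4/FC4/CP4,
  RS → left hemisphere C3/FC3/CP3, RF → midline FZ/CZ, rest → posterior
  idle rhythm P3/P4/P7/P8). The oscillation amplitude is calibrated in
  closed form so active channels exceed background 8–30 Hz band power
  by the configured gain (default gain 1, i.e. twice the background);
- blinks: raised-cosine pulses (default 200 µV peak, 0.35 s wide) at
  Poisson onsets (0.25/s), projected onto the EEG channels through a
  frontal-to-posterior decay profile (0.6 at FZ down to 0.05 at P7/P8)
  and onto VEOG at unit gain plus 2 µV measurement noise.

Defaults mirror the recording protocol: 5 subjects, 60 trials per state
(50 train / 10 test), 256 Hz, 9 s trials. Everything is a deterministic
function of the seed. The raised-cosine blink is smooth and essentially
band-limited below 8 Hz, so the band-pass alone removes nearly all of
it; the artifact-suppression diagnostics therefore measure wCCA on raw
generated trials, where frontal contamination is strong. What the
generator does *not* model: head-volume conduction beyond the fixed
decay profile, muscle artifacts, inter-subject covariance shift,
left/right-hander asymmetry, or nonstationarity across a session.
Passing tests on this data show the pipeline recovers the structure it
assumes; they do not certify performance on real recordings, where the
paper-reported accuracy levels depend on subject-specific signal
quality.

## Numerical choices and degenerate inputs

- Wavelet transform: symmetric signal extension, per-level length
  bookkeeping `floor((n + L − 1)/2)`, so arbitrary (non power-of-two)
  lengths reconstruct exactly; verified against an independent DWT
  implementation and by round-trip properties to 1e−9.
- CCA declares a block degenerate when its covariance's smallest
  eigenvalue falls below 1e−10 of the largest; wCCA refuses canonical
  bases with condition number above 1e10.
- CSP requires the composite covariance to be positive definite and
  errors otherwise; zero-energy trials and zero-variance projections
  are errors, not silent NaNs.
- Blink trains with rate 0 or amplitude 0 are exact zeros; empty
  subbands and empty epoch windows are parameter errors; epochs running
  past the end of a recording raise a "truncated epoch" warning and are
  dropped rather than zero-padded.
- The pipeline's master seed fans out by a fixed counter scheme
  (seed + 0 generation, seed + 1 fold assignment), so adding stages
  never reshuffles earlier randomness.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the protocol scale for
the end-to-end property (5 subjects × 240 trials, 50/10 split per
state, 10 seeded replicates, plus one null run with the class signal
removed) and reduced sizes elsewhere (2 subjects × 8 trials per state
with 2 s windows for structural counts and the 121-cell grid; 6-channel
random trials for the CSP oracle), keeping the whole battery
desk-scale. The null control checks that accuracy collapses to the
4-class chance level when the generator emits no class signal.

## Known limitations

- The wCCA model assumes the artifact is the dominant shared
  cross-hemisphere component; simultaneous bilateral cortical activity
  with strong mirror symmetry would be attenuated along with it.
- VisuShrink's noise-scale estimate assumes sparse transients over a
  noise floor within each subband; densely oscillatory canonical
  components violate it (hence the scope distinction between the two
  denoising paths).
- Generic learning helps when subjects share covariance structure; the
  generator draws all subjects from the same distribution, which is the
  favourable case. With strong inter-subject shift, larger `beta`
  values can hurt — the grid search exists precisely to tune this per
  subject.
- The EDF reader covers plain continuous EDF with uniform sampling
  rates and µV/mV units only.
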