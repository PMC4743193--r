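---
title: "Multi-domain feature fusion for EEG error-potential detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain feature fusion for EEG error-potential detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Brain-computer interfaces (BCIs) driven by EEG make mistakes, and the brain
of the user notices: unexpected (erroneous) feedback evokes an
error-related potential (ErrP), dominated by a fronto-central negative
deflection some 200-400 ms after feedback onset (the feedback
error-related negativity, fERN), typically followed by a later positivity.
Detecting ErrPs on single trials lets a BCI veto or correct its own output.
The difficulty is that single-trial EEG has very low signal-to-noise ratio
and the discriminative information is spread across time, frequency and
scalp location, while naively concatenating every feature of every channel
(tens of thousands of dimensions for a few hundred training trials) invites
severe overfitting.

`errpfusion` implements a detection pipeline that extracts *level-1*
features in three domains per channel and then collapses them twice with
small feed-forward neural networks — first to one posterior probability per
(domain, channel) (*level-2*), then to one posterior per domain
(*level-3*) — before a final network classifies the three-dimensional
fused representation. The same cascade also yields classifiers for every
single domain and pair of domains, which is what the per-subject AUC table
and the ablation study compare.

## Data model and preprocessing

Epochs are 56-channel (extended 10-20 montage) segments at 200 Hz, cut
from 200 to 1000 ms after each feedback event with *inclusive* endpoints —
hence 161 samples per channel. The inclusive convention is deliberate: it
is the only one consistent with the spatial feature dimension of 161 that
the projection step inherits.

Preprocessing is a fourth-order Butterworth band-pass at 1-20 Hz, applied
zero-phase (forward-backward), followed by common average referencing
(CAR) and epoching. Zero-phase filtering is the standard choice for
offline event-related-potential work because a causal pass would delay
component latencies; the effective magnitude response is the squared
one-pass response. No baseline correction is applied. An
artifact-removal stage (e.g. ICA-based ocular cleaning) is supported as a
pluggable hook — a function from recording to recording — but the default
pipeline omits it; blind source separation is intentionally out of scope.

**Numerics of the filter.** An order-4 band-pass expands to a degree-8
rational transfer function whose poles crowd near $z = 1$ when the low
corner (1 Hz) sits far below Nyquist (100 Hz); filtering with the expanded
polynomial loses several digits. The filter therefore runs as a cascade of
second-order sections obtained directly from the analog Butterworth
prototype (band-pass transform of each prototype pole, bilinear mapping,
conjugate pairing), with odd-reflection padding of about three periods of
the low corner at each end to absorb edge transients. This keeps the
operation linear to ~1e-12 relative and makes the DC response effectively
zero away from the edges.

## Level-1 features

**Temporal (164 per channel).** Per channel, the class-mean waveforms
$\bar y$ of correct ("positive") and error ("negative") training trials
serve as templates. For a single-channel epoch $x$ of length $N$ the
features are the unnormalized lagged correlation
$R_{x\bar y}(m) = \sum_{j=0}^{N-m-1} x_{j+m}\,\bar y_j$ and the lagged
covariance $C_{x\bar y}(m)$, the same sum with the full-signal means of
$x$ and $\bar y$ subtracted inside the product, for lags
$m = 0, \dots, 40$ against both templates:
$[R_p, R_n, C_p, C_n]$, $4 \times 41 = 164$ dimensions. The lag grid is a
design choice: 164 factors uniquely as four series of 41 lags, and larger
lag ranges carry more information at the cost of dimensionality. Negative
lags are omitted and nothing is normalized (a Pearson-style normalization
would discard the amplitude information the networks exploit). Templates
are fitted once on the training partition and reused verbatim at test
time.

**Spectral (12 per channel).** Each epoch channel is decomposed by
empirical mode decomposition (EMD) into intrinsic mode functions (IMFs)
by standard sifting: cubic-spline envelopes through the local
maxima/minima (natural splines; two extrema mirrored across each
boundary), envelope-mean subtraction, stopping a sift when the Cauchy
criterion $\sum (h_{prev}-h)^2 / \sum h_{prev}^2 < 0.2$ or after 100
iterations, and stopping extraction at four IMFs or when the residue is
monotonic. These are the canonical sifting defaults; the decomposition is
exactly complete (IMFs + residue reconstruct the input) by construction.
The first three IMFs are kept — at this epoch length and band-pass the
fourth is essentially a monotone residue trend — and each is summarized
by four statistics via its Hilbert analytic signal
$z_i = c_i + \mathrm{i}\,H\{c_i\} = a_i e^{\mathrm{i}\theta_i}$:

* relative energy $E_i = \sum_t a_i^2(t) \big/ \sum_{k\le 3}\sum_t a_k^2(t)$
  (for a single IMF the Hilbert spectrum has one frequency ridge per time
  point, so the frequency integral of the squared spectrum collapses to
  the squared analytic amplitude);
* mean instantaneous frequency $\Phi_i = \frac1N \sum_t \omega_i(t)$ with
  $\omega_i = d\theta_i/dt$ (unwrapped phase, central differences), in
  rad/s by default — a `freq_unit = "hz"` flag divides by $2\pi$ for
  reporting, the classifier is indifferent to the unit;
* mean slope $MS_i$, the mean first difference times the sampling rate
  (µV/s), which telescopes to $(c_i[N]-c_i[1])\,f_s/(N-1)$;
* coefficient of variation $CV_i = \sigma_i / \mu_i$. IMFs are nearly
  zero-mean, so this ratio is intrinsically unstable; the denominator is
  guarded as $\mathrm{sign}(\mu)\max(|\mu|, 10^{-12}\sigma)$. The guard
  prevents division by zero — it does not hide the instability, which the
  per-feature standardization in the network stage then bounds.

If fewer than three IMFs emerge, the missing slots are zero-filled and a
warning is emitted.

**Spatial (161 per channel).** Common spatial patterns (CSP): per-epoch
covariances $XX^\top/\mathrm{tr}(XX^\top)$ (trace normalization is
standard practice so every epoch contributes equal power) are averaged per
class into $\bar R_p, \bar R_n$; eigendecomposing
$\bar R_p + \bar R_n = U_C \lambda_C U_C^\top$ gives the whitening matrix
$P = \lambda_C^{-1/2} U_C^\top$; the whitened class matrices
$S_i = P \bar R_i P^\top$ share eigenvectors $B$ with eigenvalue pairs
summing to one, and $W = B^\top P$ holds one spatial filter per row. Rows
are ordered by the positive-class eigenvalue, descending, with ties broken
by original eigenvector index, so virtual-channel indexing is
reproducible. *All* 56 filters are kept — no manual filter selection —
because the network cascade performs the dimensionality reduction instead;
the level-1 spatial feature of virtual channel $i$ is the filtered time
course $Y_i = W_i X$ (161 samples). When the composite covariance is
ill-conditioned (condition number above 1e10) a ridge
$10^{-8}\,\mathrm{tr}(\cdot)/n_{ch}\, I$ is added before whitening;
56-channel covariances estimated from a few hundred 161-sample epochs can
be near-singular.

## The network cascade

Every unit is a single-hidden-layer feed-forward network with hyperbolic
tangent sigmoid (tansig) hidden units and one logistic sigmoid (logsig)
output unit, so outputs read directly as posterior probabilities of the
positive (correct-feedback) class in [0, 1]. The output activation is a
considered choice: a tansig output would range over (-1, 1), which is
incompatible with the posterior-probability reading of the level-2/3
features; tansig is used where it belongs, in the hidden layer.

* Stage 1: one network per (domain, channel) — 3 × 56 networks with input
  dimensions 164 / 12 / 161 and 10 hidden units — collapsing each feature
  block to a per-channel posterior. A per-channel bank (rather than one
  shared network) follows the per-channel collapse of the architecture and
  keeps each unit small.
* Stage 2: one 56-input network per domain (8 hidden units) collapsing the
  channel posteriors to the scalar per-domain posterior.
* Final: a 3-input network (4 hidden units) on the fused level-3 triplet.
  Combiner networks for all seven domain subsets are fitted alongside at
  negligible cost, so single- and pair-domain scores need no re-training.

Training is full-batch resilient back-propagation (iRprop-) on the
cross-entropy loss, at most 200 epochs, with early stopping on a
stratified 15% validation split (patience 20, best-epoch weights
restored). Rprop was chosen because it needs no learning-rate tuning
across the very different input scales of the three domains and is
deterministic given the initial weights; inputs are additionally
standardized per feature (training mean/sd stored in the model) because
the raw temporal features are unnormalized sums several orders of
magnitude larger than the spectral statistics. Initial weights and the
validation split are drawn from R's RNG, so the whole fit is bit-for-bit
reproducible from the master seed. Stage-2 and final networks are trained
on in-sample stage-1 outputs (straight stacking), matching the
architecture's data flow; the resulting optimism affects only the
*training* posteriors, and all reported performance is computed on
held-out subjects or trials. Class rebalancing is off by default (the
0.7/0.3 imbalance is part of the problem); inverse-frequency loss weights
are available in `fusion_control()`.

## Evaluation

The positive class is *correct* feedback, so under realistic ~70% correct
trials the true-positive cell of the confusion matrix is the large one;
total accuracy is TP% + TN%. ROC curves sweep every unique score; the AUC
is the Mann-Whitney statistic with half credit for ties (identical to the
trapezoidal area), invariant under monotone transforms of the scores. The
per-subject table reports AUC for all seven domain combinations plus an
unweighted average. The electrode-ablation study re-trains the complete
pipeline per electrode subset — re-using weights would understate the
contribution of added electrodes — both per single electrode and for
cumulative montage prefixes starting at FP1. With a single electrode the
CSP step degenerates to a scalar rescaling (its trace-normalized 1×1
covariances are identically 1); the spatial branch then carries the
rescaled waveform, and the precondition of two channels is relaxed for
exactly this use.

## The synthetic-data generator

Real feedback-ErrP recordings cannot ship with the package, so
`simulate_session()` generates sessions with the structure the pipeline
assumes, under the emulated study conditions: 26 subjects × 200 trials by
default, error probability 0.3, 56 channels at 200 Hz. Error trials carry
a negative Gaussian deflection (peak 300 ms, σ = 45 ms) plus a
half-amplitude positivity (peak 500 ms, σ = 60 ms — a Pe analogue);
correct trials a smaller (0.4×) positivity near 320 ms. The topography is
a fixed Gaussian bump over scalp distance from FCz (σ = 0.4 head radii) —
a weight table, not a forward model. Background noise is AR(1)
(coefficient 0.95) band-passed to 1-40 Hz per channel, plus a rank-6
spatially mixed set of shared AR sources and a common 10 Hz sinusoid with
random phase per subject (alpha analogue); each channel is rescaled to a
10 µV standard deviation, so the `snr` parameter is exactly the template
peak amplitude over the noise sd. The default `snr = 1` reflects that
single-trial ERP components are of the order of the background. Per-trial
latency jitter (sd 20 ms) and a log-normal per-subject amplitude factor
(sd 0.2) emulate trial and subject variability. Inter-trial intervals are
jittered uniformly over 1.3-1.7 s; this also prevents the alpha component
from phase-locking to feedback onsets, which would otherwise survive trial
averaging.

What the generator does *not* emulate: volume-conducted dipole physics,
ocular/muscle artifacts, non-stationary drift across a session, and
latency/shape differences between subjects beyond a scalar amplitude.
Passing tests on this generator therefore demonstrates that the pipeline
recovers a planted, topographically plausible ErrP from realistic
colored, spatially correlated noise — not that it attains any particular
accuracy on real recordings.

`simulate_complementary_epochs()` is a separate stress design for the
fusion claim: trials split into three groups whose error signatures live
(mostly) in one domain each — a fERN-shaped deflection, a random-phase
6 Hz theta burst (invisible to the class template, visible to the
spectral statistics), and extra broadband variance along a fixed spatial
pattern (a CSP signature). A single-domain classifier can only separate
part of the error trials; the fused classifier sees all three.

## Problem sizes, tolerances and known limitations

The test suite exercises the full pipeline at 10 subjects × 150 epochs ×
56 channels (6 training / 4 test subjects) for the planted-signal
recovery checks, and smaller montage subsets (2-8 channels) for
unit-level properties; these sizes keep the whole suite within a few
minutes on one CPU while leaving the per-subject trial counts at a
realistic scale. Algebraic identities (EMD completeness, CSP whitening
and simultaneous diagonalization, oracle equivalences for the lagged
statistics, AUC and confusion cells) are asserted at 1e-8 to 1e-12;
closed-form signal checks (tone amplitude/frequency, modulation
envelopes) at 2-5% in the window interior, since Hilbert amplitude and
instantaneous frequency are unreliable near segment edges.

Known limitations: EMD on 161-sample epochs frequently yields only two
IMFs (the zero-fill path is routine, not exceptional, at this window
length); the $CV$ statistic is noisy by construction; straight stacking
makes in-sample scores optimistic; training 168 per-channel networks
dominates the fitting cost; and the electrode-ablation study re-trains
the pipeline per subset, so its cost is linear in the number of subsets
studied.
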