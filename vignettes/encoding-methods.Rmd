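---
title: "Forward encoding of orientation from EEG: models, simulator, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward encoding of orientation from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Repetition suppression — the attenuated evoked response to a repeated
stimulus — is classically explained either as neuronal adaptation or, under
predictive-coding accounts, as a reduced prediction error for an *expected*
stimulus. Separating the two requires a paradigm in which repetition and
expectation are manipulated orthogonally, and an analysis that measures not
just the overall response amplitude but how much *feature information* the
neural signal carries.

`encodeEEG` implements that analysis for orientation: pairs of gratings are
shown 600 ms apart; in *repeating* blocks 80% of pairs repeat the first
grating's orientation, in *alternating* blocks 80% change it. Crossing
trial type with block context yields the 2x2 design expected/unexpected x
repeat/alternate. The package quantifies orientation-selective information
in the multichannel EEG with a forward (inverted) encoding model, follows
up with backward decoding, and performs the group-level nonparametric
inference. Because no public recording accompanies the design, the package
also contains a forward *simulator* that generates the full paradigm with
known, recoverable ground truth, so that every analysis stage can be
validated by parameter recovery rather than by eye.

## The encoding model

Orientation is modelled by nine tuned channels with centres evenly spaced
at 0, 20, ..., 160 degrees. Channel $i$ responds to orientation $\theta$
with the half-cosine profile

$$ f_i(\theta) = \cos^8\!\left(\frac{\pi\,\Delta_i(\theta)}{180}\right), $$

where $\Delta_i$ is the circular orientation difference on the 180-degree
space. The exponent must be even (an odd power breaks 180-degree
periodicity under this parameterisation, which is why `makeBasis()` refuses
odd exponents). For nine channels and exponent 8 the across-channel sum is
the constant $315/128$ at every orientation — the basis tiles orientation
space without bias, which the test suite asserts at $10^{-10}$ on a dense
grid.

For a sliding 16 ms window (4 ms steps) the sensor features $B$ (sensors x
trials; the within-window sample average, keeping the regression dimension
at sensors x channels) are related to the tuned channel responses $C$
(channels x trials, columns $f(\theta_{trial})$) by $B = WC$. The weights
are estimated by ordinary least squares on the training folds,

$$ \hat W = B\,C^\top (C C^\top)^{-1}, $$

and inverted on held-out trials,

$$ \hat C_2 = (\hat W^\top \hat W)^{-1} \hat W^\top B_2 . $$

These are the unique least-squares forms consistent with the stated matrix
shapes. Cross-validation is 10-fold by default with leave-one-out available
(`cvScheme = "loo"`); folds are assigned deterministically, round-robin
within orientation x condition strata, so every training fold contains all
nine orientations (full-rank $C$) and no random fold split enters the
pipeline. A trial never contributes to the weights that reconstruct it; the
fold bookkeeping is stored in the output and asserted in tests.

Reconstructed responses are *centered*: each trial's nine-vector is
circularly shifted so its presented orientation sits at offset 0 degrees,
allowing averaging across orientations. Selectivity is quantified by
fitting

$$ G(x) = A \exp\!\left(-\frac{(x-\phi)^2}{2\sigma^2}\right) + C $$

to the centered mean response: $A$ is the amount of orientation-selective
activity, $\phi$ the centre, $\sigma$ the width, and $C$ a non-selective
baseline.

### Numerical choices in the tuning fit

Nine data points cannot constrain arbitrarily wide or shifted Gaussians, so
the fit bounds $\sigma \in [5, 90]$ degrees and $\phi \in [-20, 20]$
degrees; the $\sigma$ bound also prevents a flat curve from being absorbed
into a huge-width Gaussian instead of $A \approx 0$. For fixed
$(\phi, \sigma)$ the model is linear in $(A, C)$, so those are profiled out
in closed form; the nonlinear part multi-starts from a deterministic
5 x 6 grid over $(\phi, \sigma)$ and polishes the best start with bounded
quasi-Newton iterations. A brute-force 4-D grid-search oracle in the test
suite verifies the fit's residual sum of squares is never beaten by more
than $10^{-6}$.

The temporal smoothing kernel ("16 ms Gaussian") is interpreted as FWHM =
16 ms (sd $\approx$ 6.8 ms), truncated at two standard deviations with
reflective edge handling, so constants pass through unchanged. Whether such
a kernel width is an SD, FWHM or support is genuinely ambiguous in common
usage; FWHM is the interpretation under which "16 ms" matches the window
length of the encoder.

## Scale invariance of the inverted encoder — what is recoverable

A property worth stating explicitly, because it determines what "parameter
recovery" can mean: the encoding regression is *scale invariant*. Training
and test features at a given time share the condition gains and the signal
envelope, so multiplying the whole signal by any factor cancels between
weight estimation and inversion. Concretely, if the injected channel
activation is $g_i\,c(\theta_i)$ per trial, the recovered test response is
$\approx (g_i/\bar g)\, c(\theta_i)$, where $\bar g$ is the mean gain over
training trials — independent of the envelope at that time point.
Consequently:

- absolute injected gains are not identifiable; gains *relative to the
  trial-mean gain* are (with the default 80/20 contingencies and gains
  0.41/0.67, the recoverable amplitudes are $0.41/\bar g \approx 0.89$ and
  $0.67/\bar g \approx 1.45$, ratio preserved);
- the per-subject gain multiplier cancels entirely, so between-subject
  variability in the *fitted amplitudes* comes from measurement noise, not
  from the simulator's gain jitter;
- for any injected profile that is a circular shift of a fixed template
  across the grid orientations, the noiseless recovered response equals the
  *basis* profile (the circulant algebra forces it), so the injected
  Gaussian width of the optional `tuningProfile = "gaussian"` mode is not
  recoverable through the encoder. The default mode therefore injects the
  encoder's own basis activation, for which noiseless recovery is exact,
  and ground truth for width is defined as the Gaussian-fit width of the
  injected profile ($\approx 19.8$ degrees).

The simulator stores the recoverable quantities (`relativeGains`, injected
profiles) in its `GroundTruth` so recovery can be scored honestly. Analysis
stages never read the ground truth; only the scoring/report stage does.

## The simulator: what it emulates and what it does not

`generateSessionDesign()` reproduces the factorial design with exact
counts: blocks of 135 trials, 108/27 contingency splits enforced exactly
(not by Bernoulli draws, which would add sampling noise to design-level
checks), second-Gabor orientations balanced across the nine-value grid
within every block x trial-type cell, 10% coloured-target trials placed
uniformly at session level (10% of 135 is not an integer, so the target
constraint lives at the session), and the first Gabor of alternate trials
drawn from the eight non-matching grid values. The exact counterbalancing
of first against second orientations in the original paradigm is not fully
specified anywhere; per-cell balancing of the second orientation plus
uniform draws for the first is the reconstruction used here.

`simulateEpochs()` builds the sensor signal as
gain(condition) x envelope(t) x forward model x channel activation, plus
white and 1/f sensor noise. The forward model assigns each channel a
circularly shifted copy of a smooth unit-norm "occipital" topography,
giving a full-rank sensors x channels matrix with known ground truth. The
envelope is zero until 50 ms after the second stimulus, rises to a plateau
over 120-250 ms and decays to zero by 470 ms (half-cosine ramps) —
matching where orientation information is reliably present in the kind of
recording this emulates.

Noise defaults are a modelling choice (no noise model is printed for the
paradigm): white 1.5 uV and pink 1.0 uV per sample per sensor, and a
log-normal per-subject gain multiplier with sd 0.1. They were chosen a
priori so that the per-condition channel-response standard error at the
reduced trial counts used on a desk (5 subjects, 6 blocks) is on the order
of 0.05 amplitude units — the order of subject-level standard errors
reported in comparable EEG encoding work. Real single-trial EEG is
considerably noisier; full-scale cohorts (15 subjects, 20 blocks x 2
sessions, leave-one-out CV) compensate with trial count, and
`fullScale = TRUE` in `runConfig()` switches to those settings.

The simulator deliberately omits: eye-blink/muscle artefacts (the upstream
artefact pipeline — ICA, bad-channel repair — is out of scope), spatially
correlated noise by default, baseline drifts, behavioural responses, and
any signal for the *first* grating. Passing tests therefore demonstrate
correctness of the analysis machinery and recoverability under the stated
signal model, not robustness to real-world artefacts.

## Preprocessing

The signal-level steps are implemented directly: common-average
re-referencing, zero-phase (forward-backward) Butterworth filtering of
documented order (the cut-offs 0.5 Hz high-pass and 2-40 Hz band-pass are
standard; the filter family is not dictated by the paradigm — zero-phase
IIR is chosen so P1/N1 latencies are not shifted), baseline correction to
the mean of -100 to 0 ms before either the second stimulus (default) or
the first (control analysis), and +/-100 uV peak-voltage trial rejection.
Re-referencing and baselining commute (both are linear projections), which
is asserted numerically. Coloured-target trials are excluded from ERP
averages but included in encoding/decoding training and test sets — the
two conventions the paradigm uses, exposed as a flag. Simulated data are
generated at 256 Hz directly; a resampling operation exists for external
recordings at higher rates but is not exercised by the acceptance runs.

The epochs container is a JSON header plus little-endian binary payload
with a CSV design sidecar — chosen over an opaque binary for
cross-language portability. The default payload is float64 so that
`readEpochs(writeEpochs(x))` is bit-exact; float32 is available where disk
size matters.

## Backward decoding

The naive Bayes classifier is the diagonal-covariance Gaussian
discriminant: per-feature class means with variances pooled across classes
("diaglinear"; a per-class-variance variant is available), uniform priors,
ties broken towards the lowest class index. Features are identical to the
encoder's (window-averaged sensors), so forward and backward results are
like-for-like. Training pools all conditions, and per-condition accuracy is
scored from the pooled classifier's held-out predictions; no trial
averaging precedes classification. Peak accuracy is the maximum of the
accuracy time course in the 600 ms after the second stimulus, per subject
and condition; chance is 1/9.

## Group statistics

Group inference uses sign-flip permutation: each subject's entire
difference series is multiplied by +/-1 with equal probability and the
one-sample t series recomputed. Cluster-mass correction forms clusters of
contiguous (1-d) or 4-connected (2-d, for cross-temporal maps)
supra-threshold points — the pointwise threshold is the parametric
two-sided t at p < 0.05, df = subjects - 1, a choice the machinery exposes
— and compares observed cluster masses against the permutation
distribution of the maximum cluster mass, with the +1 correction so p is
never exactly zero. Desk-scale defaults are 1000 permutations for time
series and 500 for generalisation maps; the full-scale 50,000/5,000 are a
flag away.

Two properties discovered while validating the machinery matter for small
cohorts. First, the identity flip pattern reproduces the observed
statistic only up to floating-point roundoff, so the null comparison uses
a small tolerance — without it, p-values can fall below their
combinatorial floor. Second, that floor is real: with $n$ subjects there
are only $2^n$ flip patterns, so a two-sided test cannot reach p < 0.05
with 5 subjects (floor $2/32 = 0.0625$). The expectation contrast is
directional (prediction error should increase selectivity, and in recovery
runs the injected direction is known), so the pipeline tests it one-sided
(floor $1/32$); the repetition and width contrasts — expected null — stay
two-sided. At the full 15-subject scale the floor ($2/32768$) constrains
nothing.

The calibration of the whole construction is itself tested: on pure-null
cohorts the family-wise error rate at nominal 0.05 must land in
[0.02, 0.09] over 200 repetitions, and the sign-flip null quantiles are
checked for uniformity.

## ERP components

For comparison with classic peak analyses, per-condition ERPs over a fixed
posterior sensor grouping are band-pass filtered 2-40 Hz and the P1 is
taken as the largest positivity 80-110 ms, the N1 as the largest
negativity 90-130 ms, after the second stimulus; ties resolve to the
earliest latency. Paired t-tests compare conditions. In the simulator,
condition-dependent gain differences propagate into these components
through the mean evoked response, so the repetition/expectation component
contrasts are qualitatively reproducible but their absolute microvolt
values are properties of the synthetic signal model, not predictions.

## Problem sizes and runtime

Desk-scale defaults are deliberate: 5 subjects, 6 blocks of 135 trials,
8-12 ms encoder steps over the 600 ms around the second stimulus, 1000/500
permutations. A full `runFullAnalysis()` at these sizes completes in a few
minutes; the recovery and calibration suites in `tests/testthat/` use the
same sizes with 20 seeds. The full-scale settings (15 subjects, 20 blocks,
two sessions, 4 ms steps, leave-one-out, 50,000 permutations) are
reachable with `runConfig(fullScale = TRUE)` but are compute-hours, not
compute-minutes.

## Known limitations

- Absolute amplitude recovery is impossible in principle (scale
  invariance, above); all amplitude claims are relative or contrast-based.
- The simulator's clean-channel assumption means artefact-robustness is
  untested; the out-of-scope upstream cleaning (ICA, bad-channel repair)
  would be required on real recordings.
- Electrode-adjacency (scalp topographic) cluster tests are not
  implemented; cluster correction is temporal (1-d) or
  train x test-temporal (2-d) only.
- The two cluster alpha conventions found in figure-level reporting
  (p < 0.025 vs p < 0.05) are exposed as `clusterAlpha` rather than
  reconciled.
- No von Mises (circular Gaussian) alternative tuning fit and no bootstrap
  confidence intervals on single fits; group inference carries the
  uncertainty.
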