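---
title: "Decoding pain reports from pre-stimulus EEG spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pain reports from pre-stimulus EEG spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When an electrical stimulus is delivered at a person's individual pain
threshold, the same physical input is sometimes reported as painful and
sometimes not.  The hypothesis this package operationalizes is that the
*state of ongoing brain activity before the stimulus* — in particular the
pattern of oscillatory power across electrodes and frequencies, with a
prominent role for high-gamma (60–120 Hz) activity over fronto-central
sites — partly determines the upcoming report.  The analysis asks: can a
linear classifier, trained on single-trial pre-stimulus EEG power spectra,
predict whether the subject will rate the stimulus above or below the pain
threshold, and which features carry that prediction?

Because the recordings the question was originally asked of are not
publicly deposited, the package pairs the full analysis pipeline with a
synthetic cohort generator that plants exactly the statistical structure
the analysis assumes.  Every stage of the pipeline is thereby testable: the
generator's ground truth is known, so decoding accuracy, band attribution,
lateralization and coupling can be checked as *recovery* problems rather
than taken on faith.

## The synthetic cohort model

`generate_subject()` simulates one subject's continuous 250 Hz recording as
the sum of three components.

**Background.** Per-channel independent Gaussian noise with a
$1/f^{\gamma}$ power spectrum ($\gamma$ = `background_exponent`, default 1)
and 10 µV RMS, frequencies below 1 Hz flattened (recordings are high-pass
filtered at acquisition).  Realized by FFT amplitude shaping of white
noise, padded to a 2-3-5-smooth length for speed.

**Pre-stimulus gamma bursts.** On every trial, each channel receives an
amplitude-modulated burst of band-pass noise under a Hann envelope spanning
the −1.5 to −0.25 s analysis window.  The carrier is the sum of two
4 Hz-wide components at subject-specific frequencies (drawn uniformly from
68–78 and 82–95 Hz): induced gamma in real EEG appears as narrow,
individually variable spectral components, and these choices keep the
bursts together with their ±4 Hz multitaper smoothing and leakage skirts
inside the 60–120 Hz band.  The burst is noise, not a sinusoid, so
multitaper smoothing behaves as it does on real induced activity.

**Latent state and report.** A per-trial scalar state $g_t$ follows a
stationary AR(1) process with unit marginal variance and lag-1
autocorrelation `trial_ar1_phi` (default 0: the working hypothesis is that
the pre-stimulus state is trial-specific).  The report is drawn from the
state through a probit link,
$\text{pain}_t = \mathbb{1}\{\lambda g_t + \sqrt{1-\lambda^2}\,e_t > 0\}$,
with $\lambda$ solved in closed form so that the standardized class
difference of $g_t$ equals `effect_size_d` (default 0.8).  A probit rather
than logistic link was chosen precisely because this calibration is exact;
the dependence structure is the same.  The channel-level state is
$h_{ct} = g_t + s_w (d_c - d)(\mathbb{1}_{\text{pain}} - \tfrac12)$, which
gives channel $c$ a standardized class difference of exactly $d_c$: the
fronto-central focus channels (Fz, FCz, FC1, FC2, Cz) carry $d_c = d$, the central
channel contralateral to the stimulated hand carries $+\delta$
(`lateralization_delta`, default $0.4d$), the ipsilateral channel
$-\delta$, and all others 0.  Burst amplitude is
$A_0 \exp(u/2) \exp(0.5\,h_{ct})$ with $A_0 = 6$ µV RMS pre-stimulus:
the gain 0.5 makes the per-cell discriminability in measured log-power
approach its ceiling (the latent-state variance) without producing the
extreme lognormal tails that degrade a margin classifier, and the burst
clearly exceeds the ~0.3 µV²/Hz background density at 80 Hz, as strongly
expressed induced gamma does.

**Post-stimulus component and coupling.** The 0.05–1 s window after each
stimulus receives an evoked gamma burst with the same carrier and base
amplitude 8 µV.  Its per-trial state has the same class-conditional
moments as $g_t$ but an independent residual: sharing the trial state
itself would add trial-mean covariance between the windows on top of the
intended subject-level coupling and inflate the realized pre/post power
correlation above its nominal value.  The subject-level amplitude factors
are lognormal, $\exp(u/2)$ with $u \sim N(0, 0.5)$, and the correlation
of the underlying normals is calibrated in closed form so that the
*power-scale* across-subject correlation — including the attenuation from
the generator's own trial-mean noise, whose log-variance is
$(e-1)/T$ for $T$ trials — equals `pre_post_coupling_rho` (default 0.85).
Pearson correlations of lognormal quantities remain somewhat
over-dispersed relative to the normal-theory Fisher interval, a property
of the estimand rather than of the pipeline.  The background has *no*
subject-level amplitude factor; this keeps the pre/post power correlation
confined to the planted gamma range, which is what the per-frequency
analysis is designed to detect.  Real recordings would show subject-level
amplitude differences at all frequencies, so the per-frequency confinement
test says less about real data than about the pipeline's selectivity.

**Ratings.** Given the class, the visual-analog-scale rating is drawn from
a truncated normal — no-pain: mean 40, SD 12 on [0, 50); pain: mean 55.2,
SD 6.4 on (50, 100] — resampled (not clipped) on truncation violations so
the forbidden midpoint 50 is never emitted and the distribution shape is
preserved.

Everything is deterministic given (`seed`, subject index); latent states
are stored in `$ground_truth` for recovery tests and never read by any
pipeline stage.  `generate_subject(..., signal = FALSE)` draws only events,
states and ratings (bit-identical to a full generation), which makes
large-sample calibration checks cheap.

A consequence of the class-mean construction worth stating plainly: the
per-channel shifts $(d_c - d)$ are applied given the class, so a
multivariate contrast across channels can read the class better than the
scalar latent state alone allows (whose own ceiling at $d = 0.8$ is about
0.65).  The planted effect is deliberately strongly expressed — realized
full-spectrum accuracies run near 0.8 — so that the recovery properties
(band attribution of the weight maps in particular, an argmax statistic
competing against ~1800 noise cells) are sharp at desk scale; real
near-threshold cohorts decode lower (~0.68).

What the generator does **not** emulate: volume conduction and realistic
channel covariance, eye-blink/muscle artifact morphology (the artifact
module is exercised with injected artifacts in tests), drifting electrode
impedances, and any post-stimulus evoked potential outside the gamma band.

## The analysis pipeline

**Epoching and windows.** Trials are cut from −2 to +2 s around each
stimulus.  Sample arithmetic uses 0-based half-open windows: a window
$[a, b)$ seconds maps to offsets
$\text{round}(a f_s) \ldots \text{round}(a f_s) + \text{round}((b-a) f_s) - 1$.
The pre-stimulus analysis window [−1.5, −0.25) s is 312 samples at 250 Hz
(1.25 s × 250 = 312.5 rounds half-to-even to 312), the post window [0, 1) s
is 250.

**Artifact screening.** Three per-trial metrics mirror routine EEG
cleaning: 1–15 Hz band power (ocular), 100–120 Hz band power (muscle), and
the maximum absolute successive-sample difference (jumps).  Band power is
the variance of the band-limited signal computed via Parseval on the trial
FFT, summed over channels; each metric is z-scored across trials.  A trial
whose any metric exceeds the threshold (default z = 4) is dropped whole.
The fixed threshold replaces an interactive per-dataset choice; 4 is
conservative enough that clean synthetic data lose almost nothing while an
injected artifact is always caught.  Whether per-trial summaries should be
accumulated over channels before or after z-scoring is not determined by
the original description; summing channel band powers first, then
z-scoring, is this package's documented choice.

**Condition split and balancing.** Ratings above 50 are pain, below 50
no-pain (50 is not a legal rating).  Trials are sorted by rating and taken
in matched numbers from both ends of the list until one class is
exhausted: the m lowest-rated no-pain and m highest-rated pain trials are
kept, m = min(n\_pain, n\_nopain).  Ties are broken by original trial
order, making the rule deterministic; balancing is idempotent.

**Multitaper spectra.** Each windowed trial/channel is mean-removed,
multiplied by each of k = 9 DPSS tapers (computed from the classical
symmetric tridiagonal eigenproblem, so rows are exactly orthonormal),
Fourier-transformed at integer frequencies 4–120 Hz (a 1 Hz grid keeps the
feature count fixed at 117 per channel for both window lengths; the DFT is
evaluated directly at grid frequencies, not at FFT bins), and squared
magnitudes are averaged over tapers, giving power in µV²/Hz.  With
NW = 1.248 s × 4 Hz ≈ 5, nine tapers are well concentrated for the pre
window; for the 1 s post window only 2·NW−1 = 7 are, and the package warns
but honours the requested nine — the smoothing/leakage trade-off is logged
rather than silently changed.  Power is averaged over the whole window:
pre-stimulus states are not time-locked, so no time-resolved output exists.

**Per-subject decoding.** Features are the flattened channel × frequency
log-power matrix.  The log is taken before standardization
(`log_power = TRUE`): single-trial multitaper power is approximately
lognormal, and on the raw scale the linear SVM's weight maps were dominated
by noise-fitting even for strongly planted effects, while log power makes
the features near-Gaussian — the geometry a linear margin classifier
assumes.  Standardization is per-fold and train-fitted by default
(subtract the training mean, divide by the training SD; `"global"` is
available for comparison), avoiding test-set leakage that the one-line
description of the original procedure would permit.  A linear soft-margin
SVM (libsvm via e1071, C = 1 — the toolbox default, as no value is
reported) is trained in a stratified, seeded 5-fold cross-validation;
accuracy is pooled over folds and tested with the exact one-sided binomial
tail against 0.5.  Fold-wise weight vectors are averaged and reshaped to a
channels × frequencies map, signed so positive weights favour the pain
class; weights are raw discriminant weights, interpreted directly as
class-separating information (not Haufe-transformed activation patterns).
For speed, each fold's standardized features are projected onto the
training row space by a thin SVD before the SVM fit: the dual problem
depends only on the Gram matrix, so decisions and weights are *exactly*
those of the direct fit (verified against a direct e1071 fit in the test
suite), while fit cost stops scaling with the 1872-dimensional feature
space.

**Group permutation test.** The group statistic is the mean over subjects
of the cross-validated accuracy.  Its null distribution is built by
permuting condition labels within each subject and re-running the full
decoding with identical settings; the p-value is
$(1 + \#\{\text{null} \ge \text{observed}\}) / (1 + B)$.  Two design
choices matter here.  First, the original description of the permutation
construction is ambiguous; within-subject label exchange is the standard
exchangeable null for this design.  Second, the fold geometry is held at
the observed stratified split and labels are permuted *within each fold*.
Within-fold permutations form a subgroup of the full permutation group, so
the test remains exact under exchangeability — and they preserve the class
balance of every training fold, which removes the well-known below-chance
bias of cross-validated accuracy under free label permutation (an
unbalanced training fold biases predictions toward its majority class,
which the complementary test fold then punishes).  With this construction
the null distribution is centred on 0.5 without any correction, matching
the behaviour expected of a calibrated test; B defaults to 500 at desk
scale and is configurable.

**Band attribution.** For each individually significant subject
(binomial p < α, default 0.05, mirroring the restriction of group-level
weight summaries to reliably classified subjects), the frequency band
containing the global maximum of |weight| is recorded; bands are theta
4–7, alpha 8–12, beta 13–24, low gamma 30–59, high gamma 60–120 Hz.  The
25–29 Hz strip belongs to no named band: it participates in full-spectrum
decoding but cannot win attribution.  Ties are broken toward the
lower-frequency band and logged.

**Lateralization ANOVA.** Mean high-gamma weights at C5 and C6 enter a
mixed two-way ANOVA (between: stimulation site; within: electrode, via
`stats::aov` with an `Error(subject/electrode)` stratum); the reported
statistic is the site × electrode interaction with df = (1, N−2).  The
planted pattern — contralateral positive, ipsilateral negative — produces
a crossed interaction.  Zero residual variance (a noise-free crossed
pattern) is reported as F = ∞, p = 0 rather than a floating-point
artifact; a completely flat pattern as F = 0.  The subject filter falls
back to all subjects, with a message, if fewer than two significant
subjects remain on a site.

**Correlations and autocorrelation.** Pre/post decoding accuracies and
FCz high-gamma mean power are correlated across subjects (Pearson, t-based
two-sided p).  The per-frequency variant correlates subject-mean pre and
post power at every grid frequency and flags p < α/117 (Bonferroni over
the grid).  The trial-series analysis computes the sample autocorrelation
of per-trial pre-stimulus high-gamma power at FCz (the power-analysis
electrode; configurable) at lags 1–20 and flags lags exceeding the
white-noise bound 1.96/√N.

## Numerical choices and degenerate inputs

* Sample counts round half to even (R's `round`), fixing the non-integral
  1.25 s × 250 Hz pre-window at 312 samples; all index arithmetic is
  0-based half-open internally.
* The usable-taper rule is `round(2NW) − 1`, the convention under which a
  1.248 s window at 4 Hz smoothing admits exactly 9 tapers.
* Zero-variance features standardize to 0 with a warning; zero-variance
  artifact metrics, constant correlation inputs, all-rejected trial sets,
  a rating of exactly 50, an empty class, and a missing channel are all
  hard errors — degenerate inputs fail loudly rather than silently.
* The SVD projection keeps singular vectors above `1e-10` of the largest
  singular value; at the trial counts involved the projection is exact to
  machine precision.
* All randomness (generation, fold splits, permutations) is seeded, and
  generation restores the caller's RNG state.

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen so the full
suite completes comfortably on one CPU: null calibration uses 20 replicate
8-subject, 16-channel, 30-trials-per-condition null cohorts with 200
permutation iterations each; effect and lateralization recovery use one
10-subject cohort at the default effect size and trial count; coupling
recovery uses 33 subjects (the original cohort size) with 20 trials per
condition; oracle-equivalence checks use 50 random signals, all
(n\_correct, n ≤ 200) binomial pairs, and 1000 random rating vectors.
These sizes are deliberately small; the recovery checks are parameterized
by the generator's defaults, not tuned to reproduce any particular
published accuracy, and accuracies at d = 0.8 are capped near the link's
Bayes limit (~0.65) regardless of decoder quality.

## Known limitations

* The generator's channels are spatially independent apart from the shared
  latent state; no volume-conduction mixing, so weight topographies are
  sharper than real ones.
* Only the gamma band carries planted structure; real pre-stimulus states
  modulate lower bands too, and theta contributions observed in real data
  have no synthetic counterpart here.
* The permutation null holds fold geometry fixed; the variability of the
  stratified split itself is not part of the null (it is part of the
  observed statistic's seed-documented definition).
* EDF/BrainVision ingestion is not implemented; the container format is a
  plain-text directory layout designed for transparency rather than
  interchange.
```{r eval = FALSE}
library(prestim)
cfg <- cohort_config(n_subjects = 10, n_trials_per_condition = 40,
                     montage = montage_16(), seed = 1)
res <- run_pipeline(pipeline_config(cohort = cfg, n_iterations = 200))
glance(res)
autoplot(res)
```
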