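# prestim

Single-trial decoding of pain reports from pre-stimulus EEG spectra.

## The problem

When electrical stimulation is delivered at a person's individual pain
threshold, physically identical stimuli are sometimes reported as painful
and sometimes not.  One explanation is that the *ongoing brain state just
before the stimulus* — the pattern of oscillatory power across electrodes
and frequencies — biases the upcoming percept.  `prestim` implements the
multivariate analysis that tests this idea, for researchers working on
pre-stimulus brain states, pain psychophysics, or EEG decoding methods:

* a **synthetic EEG cohort generator** that plants a pre-stimulus
  high-gamma (60–120 Hz) pain/no-pain effect with a fronto-central focus,
  C5/C6 lateralization by stimulation site, across-subject pre/post gamma
  coupling, and visual-analog-scale ratings in which the midpoint 50 can
  never be selected — so the whole pipeline is verifiable against known
  ground truth without access to clinical recordings;
* **preprocessing**: epoching into [−2, 2] s trials, automatic artifact
  z-scores (1–15 Hz ocular, 100–120 Hz muscle, sample-jump), whole-epoch
  rejection, and the sort-by-rating / take-matched-ends condition
  balancing rule;
* **spectral features**: DPSS multitaper power spectra (4–120 Hz, 4 Hz
  smoothing half-bandwidth, 9 tapers) of the pre-stimulus [−1.5, −0.25) s
  and post-stimulus [0, 1) s windows;
* **per-subject decoding**: stratified 5-fold cross-validated linear SVM
  (C = 1) on standardized log-power features, exact one-sided binomial
  significance, and channel × frequency weight maps signed so positive
  weights favour the pain class;
* **group inference**: within-subject label-permutation null of the group
  mean accuracy, frequency-band attribution of maximal |weights|,
  stimulation-site × electrode (C5/C6) mixed ANOVA of high-gamma weights,
  pre/post accuracy and FCz high-gamma power correlations with a
  Bonferroni-corrected per-frequency variant, and lag-1..20 trial-series
  autocorrelation of pre-stimulus gamma power.

The statistical core, in the field's notation: per subject, trials
$x_t \in \mathbb{R}^{C \times F}$ (channels × frequencies of multitaper
power) and labels $y_t \in \{\text{pain}, \text{no-pain}\}$ (VAS > 50 vs
< 50, balanced); a linear SVM decision function
$f(x) = \langle w, \log x \rangle + b$ fit per fold on standardized
features; accuracy $\hat a$ tested per subject by
$P[X \ge n_\text{correct}],\ X \sim \mathrm{Bin}(n, \tfrac12)$, and at the
group level against the permutation null of
$\bar a = \tfrac1S \sum_s \hat a_s$ with
$p = (1 + \#\{\bar a^{(b)} \ge \bar a\})/(1 + B)$.

## Worked example

```r
library(prestim)

cfg <- cohort_config(n_subjects = 10, n_trials_per_condition = 40,
                     montage = montage_16(), seed = 1234)
res <- run_pipeline(pipeline_config(cohort = cfg, n_iterations = 200))
res
#> <group_result>
#>   group accuracy 0.801 (null mean 0.498), permutation p = 0.004975
#>   10 / 10 subjects individually significant
#>   band attribution: theta=1, alpha=0, beta=1, low_gamma=2, high_gamma=6
#>   site x electrode interaction F(1, 8) = 162.52, p = 1.35e-06
#>   pre/post accuracy r = 0.25; FCz high-gamma power r = 0.98
```

Reading the output: the cohort carries a strongly expressed planted
pre-stimulus effect (standardized latent size 0.8 at the fronto-central
focus channels), so every subject decodes individually above chance and
the group accuracy of 0.80 sits far in the tail of the label-permutation
null (p ≈ 0.005, the smallest value 200 iterations can produce).  Six of
the ten significant subjects place their largest absolute classifier
weight in the high-gamma band where the effect was planted, the
C6-contralateral / C5-ipsilateral weight asymmetry yields a strong
site × electrode interaction, and the across-subject correlation of
pre- vs post-stimulus FCz high-gamma power (planted at ρ = 0.85) is
estimated at r = 0.98 for this cohort.

Tabular and graphical views:

```r
glance(res)                       # one-row tibble of group statistics
tidy(res)                         # per-subject / window / range accuracies
autoplot(res)                     # permutation null vs observed accuracy
plot_frequency_correlation(res)   # per-frequency pre/post coupling
autoplot(res$subject_results$pre_full[[1]])   # one subject's weight map
```

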