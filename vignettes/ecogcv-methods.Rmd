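---
title: "Methods: syllable decoding, capacity, and cross-frequency coupling in speech ECoG"
author: "ecogcv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syllable decoding, capacity, and cross-frequency coupling in speech ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogcv)
```

# The analysis problem

During speech production, the ventral sensorimotor cortex (vSMC) carries a
somatotopic map of the speech articulators — lips, coronal tongue, dorsal
tongue, larynx — and high-density electrocorticography (ECoG) records the
cortical surface electrical potentials over that map while a subject reads
consonant–vowel (CV) syllables aloud: 19 consonants crossed with the vowels
/a/, /i/, /u/, 57 syllable classes in all, with unequal repetition counts
(10 to roughly 100 per class). `ecogcv` implements the full analysis chain
for such recordings:

1. **Spectral features** — narrowband analytic amplitudes from a Gaussian
   filterbank, z-scored to a quiescent baseline, aggregated into canonical
   bands, and windowed around the consonant-to-vowel acoustic transition.
2. **Decoders** — multinomial logistic regression and fully connected
   softmax networks under stratified 10-fold cross-validation with random
   hyperparameter search, chance normalization, restricted tasks,
   time-resolved decoding, data-scaling and band-comparison experiments.
3. **Information content** — mutual information and channel capacity of
   classifier confusions, the uniform-error capacity approximation, and
   information transfer rates.
4. **Confusion hierarchy** — Ward clustering of soft confusion matrices and
   correlation of prediction-space distances with articulatory feature
   distances.
5. **Cross-frequency coupling** — trial-averaged amplitude–amplitude
   correlation spectra against high gamma, peri-transition power, an
   ordinary-least-squares activity threshold, and active/inactive resolved
   spectra.
6. **Synthetic data** — a seeded generator that emulates the statistical
   structure these analyses assume, so the entire chain is testable without
   access to human recordings.

Because clinical ECoG data cannot be redistributed, every empirical claim
this package makes about itself is demonstrated on synthetic data; the
published reference arithmetic (capacity formulas, window sizes, chance
levels) is checked exactly.

# Spectral features

The filterbank consists of 40 Gaussian frequency-domain filters. No
published convention fixes its constants exactly, so the package declares
one and keeps it configurable: center frequencies geometrically spaced on
[4.07, 193.2] Hz, and Gaussian bandwidths (standard deviations) that
increase semi-logarithmically — log-linear interpolation from 1.5 Hz at the
lowest center up to `cf / 7` at 40 Hz, and `cf / 7` thereafter (a constant-Q
Morlet-like regime at high frequencies). Eight centers fall inside the high
gamma range [70, 150] Hz.

The analytic amplitude is computed in the frequency domain: negative
frequencies are zeroed, positive doubled, the Gaussian weight applied, and
the magnitude of the inverse transform taken. Amplitudes are z-scored per
channel and filter against a baseline window (silent, resting), averaged
into the canonical bands theta [4–7], alpha [8–14], beta [15–29], gamma
[30–59] and high gamma [70–150] Hz, and each lower band may be resampled so
its center-frequency-to-rate ratio matches the high-gamma reference
112.5/200 — lower bands are heavily oversampled at 200 Hz, and equalizing
the ratio makes cross-band decoding comparisons interpretable. Resampling is
polyphase with a rational approximation of the rate ratio (denominator
≤ 1000, realized rate within 1%).

Trials are cut with a half-open, start-inclusive window from 0.5 s before
to 0.79 s after the consonant-to-vowel transition — exactly 258 samples at
200 Hz — and the mean of the first and last `floor(0.04 · n)` samples
(at least one; 10 of 258) is subtracted per electrode and trial as a local
amplitude normalization. All windows in the package follow the same
half-open convention, including the 42-sample peri-transition power window
(−70 ms, +140 ms) of the coupling analysis.

# Decoders

Classifiers are softmax models trained by minimizing the multiclass
negative log-likelihood: zero hidden layers is exactly multinomial logistic
regression; one to three fully connected hidden layers (tanh or rectifier)
give the deep family. Training uses Nesterov momentum with an initial
momentum fraction of 0.5 ramping linearly to a saturation value, an
exponentially decaying learning rate with a floor, inverted dropout with
activation rescaling, L2 weight decay, and per-unit max-norm clipping.
Training stops when validation accuracy has not improved for 10 epochs, and
the best-validation parameters are restored. Every stochastic element
(initialization, batching, dropout, fold assignment, hyperparameter draws)
takes an explicit seed; identical seeds give bit-identical models.

Folds are stratified: each class is split proportionally into 10 chunks,
fold *f* takes chunk *f* as its test set and the next chunk as validation
(80/10/10), so test sets are mutually exclusive and their union is the
retained data. Classes with fewer than 10 examples are excluded before
splitting. Random search draws hyperparameters from a declared space
(layers {1,2,3} or 0; widths log-uniform [32, 1024]; learning rate
log-uniform [1e-4, 1e-1]; decay [0.95, 1]; momentum saturation
[0.9, 0.99]; dropout [0, 0.7]; weight decay log-uniform [1e-7, 1e-2];
max-norm [0.5, 4]; batch size {32, 64, 128}), trains each draw on all
folds, and selects the best mean validation accuracy, ties going to the
lowest draw index.

Chance is estimated by drawing test-set predictions i.i.d. from the
training label distribution, averaged over 100 resamplings (expectation
`sum(p_i q_i)`); accuracies are reported normalized to chance because class
counts differ drastically across tasks (3 to 57). Restricted tasks
(constriction location and degree are defined only on consonant subsets)
remap both prediction and truth, drop trials whose truth lies outside the
task, count out-of-task predictions as errors, and flag the degenerate case
where no prediction lands inside the task (chance is undefined there).
Paired model comparisons use a two-sided Wilcoxon signed-rank test on
per-fold accuracies with Bonferroni correction.

One deliberate asymmetry is worth noting for the XOR-style sanity checks:
accuracy-based early stopping can lift a linear model slightly above chance
on a nonlinearly separable problem by selecting a lucky epoch (and a hard
linear decision rule can reach 75% on ideal XOR geometry by sacrificing one
cluster). When the point of a comparison is representational capacity, the
linear baseline is therefore trained to its likelihood optimum without
early stopping, where symmetric XOR carries no linear signal.

# Information content of confusions

A classifier's pooled test confusions define a channel from true to
predicted label: a conditional table `P(pred | true)` with the empirical
class frequencies as prior. Mutual information is computed directly
(`0 log 0 = 0` throughout). The exact channel capacity — the supremum of
mutual information over input priors — is computed by Blahut–Arimoto
alternating maximization, stopping when the standard upper and lower
capacity bounds agree to 1e-10 bits; the lower bound is non-decreasing and
the prior is kept strictly positive, since the supremum is over the open
simplex. The uniform-error (Wolpaw) approximation
`log2 N + P log2 P + (1 − P) log2[(1 − P)/(N − 1)]` assumes equal per-class
accuracy and uniformly spread errors; on genuinely symmetric channels it
equals the exact capacity (a property the tests verify to 1e-6), while on
structured speech confusions it need not — the published capacity table's
own 3-vowel approximate entries are not consistent with this formula
applied to the printed accuracies, so the package reproduces the formula
rather than those entries. Information transfer rate is capacity divided by
the symbol duration; the duration is an explicit parameter (the analysis
window is 1.29 s; 1.3 s is the conventional figure).

# Structure in soft confusions

The soft confusion matrix holds the mean predicted probability vector per
true class on pooled test trials — the model's learned uncertainty, which
carries strictly more structure than thresholded predictions. Rows are
clustered with Ward's method on Euclidean distances (the metric is a
declared choice; the clustering literature's `ward.D2` form is used).
The by-eye dendrogram threshold of visual analyses is replaced by a
reproducible rule: the cutoff sits in the largest gap between consecutive
merge heights. On planted block structure with balanced blocks this
recovers the partition; on real hierarchies where top-level merges dominate
the height scale, cutting at a known number of groups (e.g., the number of
major articulators) is the better-posed operation, and the planted-recovery
checks do exactly that.

Quantitatively, for every syllable the row of prediction-space pairwise
distances is correlated (Pearson by default, Spearman optional) with the
corresponding row of articulatory feature-space distances — Euclidean
distances between binary one-hot feature vectors, so same-category pairs
sit at 0 and different-category pairs at sqrt(2) — and medians with central
50% intervals are reported per grouping. Syllables on which a restricted
grouping is undefined are excluded pairwise. One caveat the synthetic
checks make visible: groupings defined only on a subset (constriction
location) can score high correlations *within their subset* even when a
coarser grouping dominates the global structure, so cross-grouping
comparisons are only made where the criterion of interest demands them
(major articulator versus vowel).

# Cross-frequency coupling, disaggregated

The coupling analysis works on the trial-averaged tensor
`D[class × frequency × electrode × time]`. For each frequency entry, the
zero-lag Pearson correlation across time with the high-gamma reference
envelope is computed per (electrode, class) pair and averaged with standard
errors — the correlation spectrum. Mean high-gamma amplitude in the
(−70 ms, +140 ms) peri-transition window gives each pair an activity value
`A`. A single ordinary-least-squares line of correlation on amplitude,
fitted over pairs with above-baseline amplitude (`A > 0`), defines the
activity threshold `A_thresh = −intercept/slope` where the fit predicts
zero correlation; pairs above threshold are "active". (The corresponding
printed objective appears as an argmax of squared residuals; the
surrounding description of an ordinary least-squares fit is what is
implemented.) Spectra recomputed separately for active and inactive pairs
reveal structure that pooled averages mask: with positive coupling planted
in a minority of active pairs and negative elsewhere, the pooled beta
correlation lies strictly between the two group values — the aggregation
artifact the disaggregation is designed to expose. The (A, C) cloud is also
summarized in nine equal-count amplitude bins (bin construction is not
fixed by any convention; quantile bins keep per-bin error bars comparable).

Zero-variance series are excluded from correlations and counted. Fits with
near-zero slope flag the threshold as undefined rather than returning an
arbitrary crossing.

# The synthetic generator

The generator's defaults state the recording conditions the analyses
assume: 86 electrodes, the full 57-syllable inventory with per-class trial
counts uniform on [10, 105], amplitudes at 200 Hz in the (0.5, 0.79) s
window (258 samples), voltage at 400 Hz. Its components:

* **Articulator map** — each articulator dominates a contiguous electrode
  block (engagement near 1) with small positive engagement elsewhere,
  emulating vSMC somatotopy.
* **Class structure** — each syllable's expected high-gamma amplitude per
  electrode is its articulator engagement scaled between an inactive level
  (−0.3 z-units; movement-unrelated cortex sits slightly below baseline)
  and an active level (2 z-units), plus a syllable-specific spatial
  modulation scaled by the `separation` dial. Beta sits below baseline
  (−0.3), as expected during movement.
* **Envelopes** — per (electrode, syllable) pair, beta and high-gamma
  envelope fluctuations are smooth log-normal processes joined by a
  Gaussian copula. The latent correlation is calibrated analytically so the
  *Pearson* correlation of the envelopes equals the configured coupling
  exactly (`rho_latent = log(1 + rho (e^{s^2} − 1))/s^2`). These
  fluctuations are shared across trials of a syllable — they survive trial
  averaging, as the coupling analysis requires — while independent
  per-trial noise (`noise_sd`) does not.
* **Coupling laws** — `two_group` plants one correlation at engaged pairs
  and another (default 0) elsewhere, letting the active/inactive dichotomy
  be planted or ablated. `graded` plants a correlation linear in the pair's
  *realized* peri-transition amplitude, crossing zero exactly at the
  configured activity threshold. The graded law is applied to the realized
  amplitude rather than the design mean deliberately: the threshold fit
  regresses correlation on measured amplitude, and planting against the
  measured quantity makes the planted crossing recoverable without
  errors-in-variables attenuation — mirroring the empirical situation,
  where the correlation–power relation is defined over the amplitudes the
  recording actually exhibits.
* **Voltage** — band-limited oscillations at canonical carrier frequencies
  whose envelopes follow the same laws, plus 1/f background, with a
  quiescent baseline segment prepended for z-scoring.

What the generator does **not** emulate: cortical geometry and electrode
spacing, inter-subject variability, artifact and line-noise channels,
broadband (arrhythmic) spectral components, phase–phase or phase–amplitude
coupling, and coarticulation dynamics within the trial window. Passing
tests on this generator therefore demonstrate that the *estimators* recover
planted structure under realistic noise — not that real cortex behaves like
the generator.

Two estimator properties surfaced by the synthetic checks are worth
recording. First, Pearson correlations over a 258-sample window of a
process smoothed at 50 ms have few effective degrees of freedom, so
per-pair correlation estimates are biased slightly toward zero and
group-mean recoveries sit a few hundredths below the planted value — within
the ±0.1 recovery band at 50 trials per class, which is why the recovery
checks use that trial count. Second, trial-shared envelope fingerprints
make classes separable to a decoder even at zero mean separation; the
separability-dial check therefore disables the shared fluctuations so that
accuracy reflects the class means alone.

# Problem sizes and runtime choices

The test suite and reproduction script run on one CPU in a few minutes.
Sizes were chosen as the smallest that make each property statistically
unambiguous: coupling recovery uses 10–12 electrodes with 24–57 classes
(240–684 electrode–class pairs, ≥ 500 for the threshold fit) at 25–50
trials per class; decoder checks use a few hundred trials in 2 dimensions;
capacity properties use 200 random channels of up to 8 classes; hierarchy
checks use the full 57-syllable inventory. The full-scale defaults (86
electrodes, up to 105 trials per class) run the same code paths unchanged.

# Known limitations

* The filterbank constants are a declared convention, not a reconstruction
  of any specific recording system's filters.
* The trainer is plain R matrix arithmetic: adequate for the feature sizes
  here (tens of thousands of features, thousands of trials), but not a GPU
  training stack; convolutional and recurrent architectures are out of
  scope.
* Capacity estimates treat the pooled confusion table as the channel; no
  correction is made for the finite test-set size of each class.
* The hierarchical-clustering threshold rule is one reproducible choice
  among several; conclusions should be stated at a known cluster count
  where possible.
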