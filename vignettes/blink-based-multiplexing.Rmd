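---
title: "Blink-based multiplexing: models, statistics, and design choices"
author: "blinkMux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink-based multiplexing: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkMux)
```

## The problem

Under continuous illumination a single fluorophore does not emit steadily: it
switches stochastically between emissive (on) and non-emissive (off) states,
often through several distinct emissive intensity levels, until it
photobleaches. These blinking dynamics are a fingerprint of the underlying
photophysics — electron transfer to and from trap states, excited-state
proton transfer, spectral diffusion, charging of a nanocrystal — and
blink-based multiplexing (BBM) exploits them to classify spectrally
overlapped emitters with a single excitation laser, where conventional
color-based multiplexing fails.

`blinkMux` implements the complete analysis chain on binned photon-count
traces (the acquisition unit: integer counts per fixed time bin, typically
10 ms over 150 s):

1. simulation of labelled blinking traces under mechanistic duration models;
2. change-point detection (CPD) of statistically significant intensity
   changes;
3. extraction of ten per-molecule blinking statistics;
4. maximum-likelihood fitting of heavy-tailed event-duration distributions;
5. multinomial logistic classification with probability thresholding and
   data-retention analysis.

## Mechanistic duration models

Event durations are drawn from families tied to blinking mechanisms:

* **Lognormal** (parameters $\mu$, $\sigma$ on $\log_{10}$ of the duration
  in seconds): dispersive electron-transfer kinetics in the Albery picture,
  where activation barriers are normally distributed. $10^{\mu}$ is the
  median event duration and $\sigma$ measures kinetic dispersion;
  $-\mu_{on}$ and $-\mu_{off}$ are proportional to the average forward and
  back ET rate constants. We interpret the parameters in $\log_{10}$
  seconds: reported magnitudes such as $\mu_{off} \approx -1.3$ against
  event durations running from tens of milliseconds to hundreds of seconds
  are only consistent with a base-10 logarithm. The base is a documented
  convention of every input and output.
* **Weibull** (survival $e^{-(t/\lambda)^{k}}$): stretched-exponential
  off-time kinetics associated with ESIPT photoprotection.
* **Exponential**: first-order (triplet-state) blinking; included as the
  null against which heavy tails are judged.
* **Power law / truncated power law** (density $\propto
  t^{-\alpha}e^{-\Lambda t}$ above $x_{min}$): quantum-dot intermittency.
  Pure power laws are sampled by inverse CDF; the exponential cutoff is
  imposed by rejection, which is exact and directly testable.

### The trace generator

[simulateMolecule()] realizes an alternating renewal process from these
families, then renders it through a Poisson forward model
([renderTrace()]): each bin's count is Poisson with mean equal to the
time-weighted average of the active emission rate over the bin, so bins
straddling a switch receive the correct mixture. Shot noise is therefore
exact, not additive Gaussian.

Three aspects of real traces have no published quantitative model, and the
defaults here are explicit package choices, not inferences from data:

* **Emissive-level multiplicity.** Real traces are non-binary, with several
  distinct emissive intensities per molecule. The generator draws the
  number of levels from a small-support distribution (1–7, default mode at
  4) with i.i.d. gamma-distributed level rates above background, and
  switches levels at on-segment boundaries drawn from the same on-duration
  family. This reproduces on–on switching without asserting a mechanism.
* **Photobleaching** is a single irreversible off transition at an
  exponentially distributed time (mean 25 s for rhodamine-like classes,
  reflecting their typical single-step bleaching within tens of seconds;
  70 s for the photoprotected ESIPT class; none for quantum dots).
* **Dispersion parameters not individually established** (the off-interval
  $\sigma$ of R560 and R123, the ESIPT Weibull shape/scale, the quantum-dot
  exponents and cutoffs) are set to values representative of their class
  ranges in [presetSpec()] and are plainly labelled as such.

Every random quantity derives deterministically from one master seed with a
documented per-molecule derivation, so populations are bit-reproducible.

Because the generator draws from exactly the families the fitter assumes,
passing parameter-recovery tests demonstrates correctness of the estimators
and the pipeline plumbing — not that real traces follow these laws. What the
synthetic populations deliberately do not contain: spectral diffusion as a
continuous drift (level switches are discrete), detector afterpulsing or
dead time, focal drift, and any correlation between successive event
durations.

## Change-point detection

Thresholding binned traces is known to bias blinking statistics, so
segmentation uses a generalized likelihood-ratio test under a per-bin
Poisson model. For a working region of $n$ bins the statistic at split $k$
is twice the difference between the two-rate and one-rate profile
log-likelihoods; the maximizing split is accepted when the statistic
exceeds a critical value, and detection recurses on both sides
([detectChangePoints()]).

Numerical choices:

* **Critical values** are the $(1-\alpha)$ Monte-Carlo quantiles of the
  maximal statistic over constant-rate Poisson traces, tabulated on a grid
  of region sizes and interpolated linearly in $\log n$
  ([estimateCriticalValues()]). The null quantile depends only weakly on
  the rate above about one count per bin (we verified a spread of a few
  percent between rates 1 and 20), so one reference rate (default
  5 counts/bin, recorded in the table metadata) suffices. Default
  $\alpha = 0.05$; the tables carry their replicate count and seed.
* **Minimum segment length** is 2 bins: the two-rate MLE is undefined on an
  empty side, so candidate splits adjacent to a region boundary are not
  considered.
* **Ties** in the maximal statistic break toward the smallest bin index.
* An all-zero or constant trace returns a single segment, not an error.

Segments are then grouped into distinct intensity levels by agglomerative
merging ([groupLevels()]): intensity-adjacent levels merge while the BIC of
the merged Poisson model is at least as good (twice the profile
log-likelihood drop below $\log n_{bins}$, the penalty for one rate
parameter). The grouped level count is the $N_I$ statistic. Finally
([labelOnOff()]) the lowest level is denoted off and a level is on when its
mean exceeds the off mean by more than one standard deviation of the rms
noise, estimated by default from the bins of the lowest level; levels
failing the criterion are merged into off. $N_I$ is preserved from the
grouping stage, before any dim level is absorbed.

## Blinking statistics and the event taxonomy

A *segment* is an event at one constant intensity; an *interval* is a
maximal run of same-state segments bounded by on/off switches. The ten
per-molecule statistics are $N_I$, $I_{min}$, $I_{max}$ (over on levels
only), $\langle I\rangle_t$ (duration-weighted over the whole trace,
including off time), $\langle t_{on,seg}\rangle$,
$\langle t_{off,seg}\rangle$, $\langle t_{on,int}\rangle$,
$\langle t_{off,int}\rangle$, $N_{on,seg}$ and $N_{off,seg}$.

**Censoring policy.** The first and last intervals of a trace are truncated
by the acquisition window. Whether to include them in per-trace statistics
is genuinely open; the package includes them in counts and averages (so the
statistics are defined for every molecule, including one long censored on
event) but excludes them from duration-distribution fitting, where
censoring visibly biases heavy-tail parameters. Both choices are
configurable (`includeCensored`), and the policy travels with every pooled
dataset. Statistics with empty support (e.g. a trace with no on event) are
set to 0 and flagged rather than dropped, so the classifier sees every
molecule.

Intensities are reported in counts per bin, the acquisition unit; durations
in seconds.

## Duration-distribution fitting

Pooled interval durations of a class are summarized as a complementary
cumulative distribution function $P(T \ge t)$ and fitted by maximum
likelihood ([fitMLE()]), with Kolmogorov–Smirnov distances and
parametric-bootstrap p-values ([goodnessOfFit()]) in which every bootstrap
replicate is refitted before its distance is measured.

* The lognormal MLE is the closed-form log-moment estimate (population
  denominator), which doubles as an exact oracle identity in the tests.
* `fitFloor` conditions the likelihood on $t \ge$ floor: events shorter
  than one bin cannot be observed, so the pipeline fits truncated
  likelihoods with the floor at the bin time. The bare function defaults to
  `fitFloor = 0` because its other role is parameter recovery on complete
  simulated samples; the pipeline always passes the bin time.
* Family ranking ([selectFamily()]) uses BIC by default, which reduces to a
  log-likelihood ordering between families of equal parameter count and
  penalizes the extra parameter otherwise; KS quantities are reported but
  do not drive the ranking, since neither criterion has printed precedence
  in the source analyses. `criterion = "loglik"` is available.
* $x_{min}$ of the power-law families is fixed at the larger of the sample
  minimum and the floor, not estimated.

## Classification

The decision model is multinomial logistic regression on z-scored
statistics: the probability of class $j$ is
$$P_j = \frac{e^{m_j N_I + n_j I_{min} + \ldots + b_j}}
             {\sum_{k=1}^{K} e^{m_k N_I + n_k I_{min} + \ldots + b_k}},$$
with the last class as the pivot whose coefficients are zero. The fit
([fitMLR()]) maximizes the penalized multinomial likelihood by BFGS with
analytic gradient from a zero start — deterministic by construction — with
a small default ridge ($10^{-6}$) on the weights so perfect separation
cannot push coefficients to infinity. An independent multinomial fitter
(`nnet::multinom`) serves as a cross-check in the test suite, never as the
implementation.

**Leakage.** Establishing coefficients on the full dataset and then
cross-validating would let test molecules influence normalization and fit.
The package therefore reports both objects separately: full-data
coefficients for interpretation (the analog of a printed discriminant), and
strictly fold-internal fits — z-scoring included — for every accuracy
number ([crossValidate()], stratified 10-fold by default).

**Decision rule and retention.** The default rule is the probability argmax
(binary: $P_A > 0.5$), ties broken toward the earlier class label. The
*minimum classification accuracy* is the minimum per-class recall at this
rule; the overall pooled accuracy is reported alongside. Raising the
threshold discards "uncertain" molecules (retained iff $\max_j P_j \ge$
threshold, the binary rule generalized); [thresholdCurve()] reports
accuracy over the retained set together with overall *and per-class*
retention, because a threshold can empty one class and silently reduce a
ternary problem to a binary one — [findThreshold()] warns when any class
retains less than half the overall retention. Classes with $n \le 10$
molecules trigger an explicit instability flag: at such sizes
cross-validated accuracy is no better than guessing.

## Problem sizes and calibration checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen so each check is statistically decisive: duration-parameter
recovery uses $n = 5000$ durations per replicate with medians over 20
seeds, judged against three-standard-error bands; classifier calibration
uses 150 molecules per class (the scale of the experimental datasets) over
20 seeds; CPD false-positive calibration uses 1500–2000 Monte-Carlo
replicates for the critical values and 200 fresh constant traces per
region size. The dispersion check restricts simulated dispersive-ET off
durations to the observable window [bin time, 150 s] and verifies that the
0.5th–99.5th percentile range still spans at least four decades.

## Known limitations

* The CPD stage commits to a specific, fully testable construction
  (Poisson likelihood per bin, recursive bisection, Monte-Carlo critical
  values, BIC level grouping); published binned-data CPD variants differ in
  detail, so absolute segment counts may differ from other implementations
  even when the detected switches agree.
* Experimental accuracies for specific dye pairs are not reproducible here:
  they depend on the original traces, which are not deposited. The package
  reproduces the *procedures* and verifies them on generators parameterized
  by the printed duration-distribution values.
* No photon-by-photon analysis: everything assumes binned counts.
* The mechanism presets are starting points for simulation studies, not
  measured properties of the dyes beyond the printed lognormal parameters.
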