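# blinkMux — blink-based multiplexing of single-molecule emitters

Single fluorophores under continuous illumination *blink*: their emission
switches stochastically between bright (on) and dark (off) states, through
multiple distinct intensity levels, until photobleaching. Blink-based
multiplexing (BBM) turns this nuisance into an identifier — spectrally
overlapped emitters excited by a single laser are classified by their
blinking dynamics rather than their color. `blinkMux` is an R package for
scientists doing single-molecule spectroscopy and localization microscopy
who want to analyze (or simulate) binned emission-time traces and quantify
how well blinking separates emitter classes.

## What it computes

Given integer photon counts per fixed time bin (e.g. 10-ms bins over 150 s)
for many molecules:

1. **Change-point detection.** Recursive generalized likelihood-ratio
   segmentation under a per-bin Poisson model, with Monte-Carlo critical
   values per region size; segments are grouped into distinct intensity
   levels by BIC and labelled on/off (lowest level is off; a level is on
   when its mean exceeds the off mean by one noise standard deviation).
2. **Blinking statistics.** The ten per-molecule statistics:
   N<sub>I</sub>, I<sub>min</sub>, I<sub>max</sub>, ⟨I⟩<sub>t</sub>,
   ⟨t<sub>on,seg</sub>⟩, ⟨t<sub>off,seg</sub>⟩, ⟨t<sub>on,int</sub>⟩,
   ⟨t<sub>off,int</sub>⟩, N<sub>on,seg</sub>, N<sub>off,seg</sub> —
   where a *segment* is an event at one intensity and an *interval* is a
   maximal same-state run of segments.
3. **Duration-distribution fitting.** CCDFs of pooled event durations and
   maximum-likelihood fits of mechanistic families — lognormal
   (dispersive electron transfer; parameters in log10 seconds), Weibull
   (ESIPT), exponential, and (truncated) power laws (quantum dots) — with
   Kolmogorov–Smirnov statistics and parametric-bootstrap p-values.
4. **Classification.** Multinomial logistic regression on z-scored
   statistics,

   P<sub>A</sub> = e<sup>(m<sub>A</sub>N<sub>I</sub> + n<sub>A</sub>I<sub>min</sub> + … + b<sub>A</sub>)</sup> / Σ<sub>j</sub> e<sup>(m<sub>j</sub>N<sub>I</sub> + n<sub>j</sub>I<sub>min</sub> + … + b<sub>j</sub>)</sup>,

   with stratified 10-fold cross-validation (fits and normalization
   strictly fold-internal), confusion matrices, minimum per-class accuracy,
   and probability thresholding with accuracy / data-retention curves.
5. **Simulation.** A first-class generator of labelled traces: alternating
   on/off renewal processes from the duration families above, multiple
   emissive levels, exact Poisson shot noise, and class-dependent
   photobleaching — so every stage is testable without experimental data.

## Worked example

Simulate a dispersive-ET rhodamine-like class (R6G preset) against an
ESIPT anthraquinone-like class (AZ preset), run the full chain, and ask how
much data must be discarded for 80 % accuracy:

```r
library(blinkMux)

specs <- list(presetSpec("R6G"), presetSpec("AZ"))
pop   <- simulatePopulation(specs, nPerClass = 40, window = 60, seed = 42)

tab   <- estimateCriticalValues(c(8, 30, 120, 500, 2000, 6000),
                                alpha = 0.05, nReplicates = 1000, seed = 1)
stats <- computeStatTable(pop, table = tab)

rep <- crossValidate(stats[, statNames()], stats$class_label,
                     folds = 10, seed = 1)
rep
#> ClassificationReport: accuracy 76.2%, min per-class 72.5%
#> Confusion (rows = true):
#>      predicted
#> true  AZ R6G
#>   AZ  29  11
#>   R6G  8  32
#> TPR 0.72, FPR 0.20

findThreshold(reportThresholdCurve(rep), 0.80)[c("threshold", "accuracy",
                                                 "retention")]
#> $threshold
#> [1] 0.65
#> $accuracy
#> [1] 0.8059701
#> $retention
#> [1] 0.8375
```

At the default argmax rule the two classes separate with 76 % pooled
accuracy (73 % for the worse class); discarding molecules whose maximum
class probability falls below 0.65 raises accuracy over the retained set to
81 % while keeping 84 % of the data. Pooled off-interval durations refit
their generating lognormal law:

```r
evs  <- lapply(pop[stats$class_label == "R6G"],
               function(tr) buildEventTable(segmentTrace(tr, tab)))
offs <- poolDurations(evs, state = "off", kind = "interval")
fitMLE(offs, "lognormal", fitFloor = 0.01)
#> DistFit [lognormal], n = 21 (conditioned on t >= 0.01 s)
#>   mu = -0.58, sigma = 0.8166
#>   logLik = -16.08, KS D = NA, KS p = NA
```

(21 uncensored off intervals from 40 short traces is far below the pooled
sample sizes used for real fits; `scripts/acceptance.R` does the recovery
properly at n = 5000.) `runPipeline(pipelineConfig(...))` chains all stages
and writes the statistics table, duration-fit report, model, confusion
matrix, threshold curve and a provenance record to an output directory.

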