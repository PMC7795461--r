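---
title: "Classifying honeybee worker status from e-nose sensor arrays: methods and design"
author: "beeNose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying honeybee worker status from e-nose sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeNose)
```

## The problem

A long-term queenless honeybee colony develops physiological laying workers
— workers that lay unfertilized eggs — and without intervention the colony
collapses. The condition is hard to recognize by eye, but the colony's
odour changes with the biological status of its workers. An electronic nose
(a small array of partially selective metal-oxide gas sensors) can in
principle detect this change without any chemical separation of the
volatile fraction.

beeNose implements the complete data-analysis pipeline for such a study:
samples of 100 workers are measured in a test chamber by a six-sensor TGS
array, each measurement being 600 s of exposure to the sample followed by
600 s of filtered ambient air (sensor regeneration), sampled once per
second. Four decision classes are used: an empty chamber (class 1), young
workers 0–1 days old (class 5), old workers 3–6 weeks old (class 6), and
workers from colonies with laying workers (class 7). Measurements are
repeated on two twin devices (M1, M2) and with two chamber inserts (wooden,
polystyrene) that mimic hive construction materials.

The original device recordings are not public, so the package includes a
synthetic-data generator that emulates the statistical structure the
analysis assumes, and ships the published benchmark metric tables from the
original measurement campaign as plain-text reference data
(`referenceResults()`); those reference numbers were measured on the
proprietary recordings and are a qualitative yardstick only — the synthetic
pipeline is not expected to reproduce them point-wise.

## The synthetic measurement model

`generateMeasurement()` draws one object's recording as

$$x^{exp}_{t,s} = \beta_{d,s} + \gamma_{i,s} + A_{c,s}\left(1 - e^{-t/\tau_r}\right) + \varepsilon_{t,s}, \qquad
  x^{reg}_{t,s} = \beta_{d,s} + A_{c,s}\, e^{-t/\tau_d} + \varepsilon_{t,s},$$

with $t = 1,\dots,600$ s, sensors $s = 1,\dots,6$, device baseline
$\beta_{d,s}$, insert odour shift $\gamma_{i,s}$ (exposure only — the
regeneration air passes a carbon filter), class plateau amplitude
$A_{c,s}$, and i.i.d. Gaussian noise
$\varepsilon \sim N(0, \sigma^2)$.

Parameter choices and their rationale:

* **Time constants** `tauRise = tauDecay = 40` s. The validity check
  enforces $e^{-270/\tau_r} < 0.01$, so the exposure signal has flattened
  to within 1% of its plateau well before the 270-s reference second —
  matching the rapid signal stabilization the protocol relies on. 40 s
  gives $e^{-270/40} \approx 0.0012$.
* **Amplitudes**. Class 1 (empty chamber) is pinned at zero. The three bee
  classes use fixed base profiles in the order young < old < laying-worker
  on every sensor (tens of sensor units above a baseline of 145–230
  units); the raw signal scale is a convention, not an estimate — no raw
  magnitudes were ever published for this device class.
* **`separation`** rescales the differences of the three bee-class
  amplitude profiles about their mean: `separation = 2` gives essentially
  separable classes, values near 0.05 give strongly overlapping ones.
  This is the single knob tests use to construct easy and hard datasets;
  class 1 is unaffected (it stays at zero).
* **Noise** defaults to 1% of the largest (post-separation) amplitude,
  per second and sensor. At the default `separation = 1` the classes are
  nearly separable; realistic difficulty is explored by lowering
  `separation`, not by inflating noise.
* **Seeding**. Every object's noise stream is seeded by hashing
  (master seed, device, insert, class, replicate), so a study is
  bit-reproducible element-wise and independent of generation order, with
  no reliance on global RNG state.

What the generator deliberately does **not** model: sensor chemistry
(humidity, heater power, ppm response curves), drift across days,
channel-switching schedules, or warm-up transients. Passing tests on
synthetic data therefore demonstrate the correctness of the analysis
pipeline — feature extraction, classifiers, evaluation arithmetic — not
the field performance of a physical device.

## Features and baseline correction

`extractFeatures()` reduces each recording to six descriptors: the
exposure reading of each sensor at a reference second, 270 s by default
(1-based, matching the 1 Hz sampling). With `baselineCorrect = TRUE` the
ambient-air reference level is subtracted: the arithmetic mean of the
object's own 600-s regeneration phase. Two readings of that rule were
possible — a single late regeneration sample or an aggregate — and the
package commits to the mean because a set of ambient values subtracted
from one reading implies aggregation and the mean is the noise-robust
choice; the single-sample alternative remains available as
`baselineStat = "last"`. The regeneration phase of the same object is used
as the ambient reference because it is the only 600-s ambient-air record
attached to each measurement. A window-mean option (`smoothWindow`) exists
but defaults to a single reading, since the protocol names a single
reference second.

In the noiseless limit the corrected descriptor is

$$A_{c,s}\left(1 - e^{-270/\tau_r}\right) - A_{c,s}\,\overline{e^{-t/\tau_d}} + \gamma_{i,s},$$

which removes the device baseline exactly — the property the
baseline-correction tests assert. Note the regeneration mean is the
*discrete* average $\frac{1}{600}\sum_{t=1}^{600} e^{-t/\tau_d}$ (a
geometric sum); the continuum integral
$(\tau_d/600)(1 - e^{-600/\tau_d})$ differs from it by about 1% at
$\tau_d = 40$, so exact tests use the discrete form.

`buildDecisionTable()` assembles the per-object descriptors of one device
× insert run into a `DecisionTable` — a `SummarizedExperiment` whose
`"features"` assay is the 6 × N matrix and whose `colData` carries the
categorical decision class. The eight test options are the cross of
device, insert and correction flag (`optionCatalogue()`).

## Class signatures

`classSignature()` computes the radar-chart signature: per attribute,
min–max normalization of all rows into $[a, b] = [0, 1]$ (extrema taken
over the whole table, all classes pooled), then the within-class mean,
then its square. A degenerate attribute (zero range) maps to $a$
everywhere. The signature is invariant to positive affine rescaling of any
raw attribute, and squaring preserves the ordering of the non-negative
class means — both are tested properties.

## The ten classifiers

All classifiers are lazy (the "training" table is the model), total
(coverage is identically 1) and deterministic: every tie — equal
distances, equal vote sums, equal scores — is broken by ascending class
label, with merged rest labels ordered numerically after the single
digits.

* **1-NN** under four metrics: Euclidean, Manhattan, Canberra
  ($\sum_i |x_i - y_i|/(|x_i| + |y_i|)$, 0/0 terms contributing 0 — the
  standard convention), and max–min-normalized Euclidean (coordinates
  scaled by the training-table ranges; a constant attribute maps to 0;
  out-of-range test values are not clipped).
* **Weighted voting "811"**: every training row votes for its own class
  with weight $1/(d + \delta)$, $\delta = 10^{-10}$; the largest vote sum
  wins. The historical definition of this rule lives in software that is
  not publicly specified, so the inverse-distance form here is a
  documented convention of this package, parameterized by the same four
  metrics so the canonical names (`canberra.811` … `maxminnormalized.811`)
  are meaningful. As $\delta \to 0$ with the query on a training row, 811
  reduces to 1-NN — a tested limit.
* **$\varepsilon$-indiscernibility Naive Bayes** (`nb`, `nb2`): per class
  $c$ and attribute $i$, the indiscernibility ratio $r_{c,i}$ is the
  fraction of the class's rows whose value lies within
  $\varepsilon \cdot (\max_i - \min_i)$ of the query
  ($\varepsilon = 0.01$); scores are *summed* over attributes rather than
  multiplied, avoiding zeroed products. `nb` scores $\sum_i r_{c,i}$; the
  two variants were never formally distinguished in public descriptions,
  so `nb2` is defined here as the class-prior-weighted sum
  $(n_c/N)\sum_i r_{c,i}$, kept behind the same interface so the
  convention is replaceable.

## Evaluation

`makeSplitPlan()` draws 5 × 5 = 25 independent stratified random splits
(the 5xMCCV5 design; every table caption's "average classification result
from 25 tests" fixes 25 as the repetition count). The train/test
percentage was never published; the default is 50/50 per class
(`round(testFraction * n_class)` test rows), configurable. One plan is
reused for every classifier, so all techniques see identical subsets, and
the sweep derives each plan seed from (device, insert, variant) —
deliberately excluding the correction flag, so each baseline-corrected
option is evaluated on exactly the splits of its uncorrected twin and
correction effects are paired. Because the split percentage is
configuration, published accuracies are not point-reproducible and are
treated as qualitative references.

`metricsFromPredictions()` follows the study's conventions: per-class
accuracy is recall; *true positive rate* is the precision analogue
(correct class-c predictions over all objects predicted c, defined as 0
when nothing is predicted c — a convention for a corner the source leaves
open); balanced accuracy is the unweighted mean of per-class accuracies
(an identity asserted to 1e-12 per split); coverage is the fraction of
objects classified, identically 1 here. Per-split records are averaged
arithmetically over the 25 splits.

`runOptionSweep()` crosses options × variants (all classes, or one class
against the merged rest, e.g. `7vsall` → classes {7, "156"}) ×
classifiers, and `sweepBest()` / `sweepSpread()` reproduce the
best-classifier and best-minus-worst summaries.

A structural note worth knowing when reading one-vs-rest results: 1-NN
predictions are invariant under merging of the rest classes (the nearest
training row does not move when rows are relabeled), so for `1nn`
classifiers the class-7 true positive rate is *identical* between the
4-class and 7-vs-rest tasks on the same splits. The vote-pooling
classifiers (811, nb2) are not invariant — merging pools the rest classes'
vote mass, which typically depresses class-7 calls in the binary task.
Both behaviours are asserted in the test suite.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full published design
where it matters — 160 objects (4 classes × 10 replicates × 2 devices × 2
inserts) and 25-split MCCV — and smaller 3–5-replicate studies for
unit-level checks; a full option × variant × classifier sweep at the
published size takes on the order of ten seconds. Other numerical
conventions: distances compare with exact floating equality for tie
detection (ties arise from identical rows, which exact equality catches);
the Canberra 0/0 and max–min zero-range conventions are as above; CSV
readings are serialized with six decimals, so a round trip is exact to
5·10⁻⁷.

## Known limitations

* The 811 and nb/nb2 rules are committed conventions (documented above),
  not reconstructions of the unpublished originals.
* The generator's scales are conventions; only relative structure
  (class ordering, device offsets, insert shifts, stabilization) is
  meaningful.
* Reference tables are shipped for the four M1-device one-vs-rest options
  only, which is what the published material tabulates row-by-row.
* No significance testing between classifiers and no ROC analysis; the
  evaluation surface is the metric tables themselves.
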