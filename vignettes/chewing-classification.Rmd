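---
title: "Classifying chewing patterns from FBG jaw-strain signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chewing patterns from FBG jaw-strain signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgchew)
```

## Scope

`fbgchew` classifies ruminant ingestive behavior — dietary supplement, hay,
ryegrass, rumination and idleness — from the jaw-bone strain signal of a
fiber Bragg grating (FBG) sensor. Because no public recording of such a
deployment exists, the package pairs the analysis chain with a synthetic
signal generator whose defaults encode the published characteristics of each
behavioral class. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic stand-in can and cannot
establish.

## The sensor model

An FBG reflects a narrow band centred on the Bragg wavelength; strain shifts
it linearly. The package uses

$$\lambda(t) = \lambda_B + k\,\varepsilon(t),$$

with $\lambda_B = 1541$ nm and $\varepsilon$ in µm/m. The published
deployment never states its strain calibration, so $k$ defaults to 1.2 pm
per µm/m, a typical value for silica gratings near 1550 nm; it is
configurable in `sensor_model()`, and `decode_strain()` is the exact
inverse, so all strain-level statements survive the wavelength round trip to
floating-point accuracy. Temperature cross-sensitivity, interrogator noise
spectra and long-term drift are deliberately out of scope.

## The class-conditional waveform

Each chew cycle is one jaw open–close movement: a positive aperture peak
followed by a closure trough, returning to a class-specific DC baseline. The
generator uses a raised-cosine aperture pulse over the first 60 % of the
cycle and a trailing negative half raised-cosine trough over the remainder,
with trough depth `trough_fraction` (default 0.3) of the peak. No analytic
waveform is published; this shape was chosen as the simplest smooth form
with the documented peak-then-trough morphology, and it concentrates the
spectral energy at the chew fundamental (bin 1 dominates bins 2–29 for every
default class, with or without the inter-movement gap), which the feature
model relies on.

Default class profiles (`default_profiles()`):

| class | peak (µm/m) | DC (µm/m) | fundamental (Hz) |
|---|---|---|---|
| dietary supplement | 50 | 30 | 2.49 |
| hay | 178 | 40 | 1.66 |
| ryegrass | 100 | 35 | 2.00 |
| rumination | 42 | 15 | 1.66 |
| idleness | 12 | 5 | 1.54 |

Peaks and fundamentals are the published per-class values. The DC offsets
are not published beyond their ordering (idleness < rumination < feeding
classes); the defaults satisfy that ordering with gaps wide enough that the
per-second mean remains class-informative under the default noise. Cycle
amplitude and period carry Gaussian jitter with coefficient of variation
0.05, and samples carry additive Gaussian noise of 2 µm/m — values chosen
once so the per-class strain histograms remain essentially disjoint, as the
published histograms are. Ryegrass is reported both near 100 µm/m and near
60 µm/m; this is modeled as within-class spread by giving ryegrass a larger
amplitude jitter (CV 0.15), so its cycle peaks range down toward ~60 µm/m,
which is also what makes it confusable with the dietary supplement — the
same confusion pair the published matrix shows.

Sessions (`generate_session()`) concatenate movements in a declared class
order. Each movement is preceded by a 0.1 s baseline gap at its class DC,
and the session ends with a 2 s baseline tail. Two details are deliberate:

- **Lead-in rather than trailing gaps.** A class segment then ends at its
  last chew cycle. At a transition to a class with a lower signal level the
  running mean falls; a trailing gap held at the *old* (higher) DC would
  rise through that falling mean and fabricate a movement that contains no
  chew at all. With lead-in gaps the transition instead rests on the new
  class's lower DC, which stays below the mean.
- **The terminal tail.** The last cycle of a session is only delimited once
  the detrended signal returns to zero. Within the tail the averaging
  window eventually lies entirely in baseline, where the detrended value is
  exactly zero (see the anchoring note below), which closes the final
  movement deterministically even in noise-free runs.

All randomness flows through the seed in `session_spec()`; the caller's RNG
state is saved and restored, and identical specifications are bit-identical.

## Segmentation

Movements are delimited where the mean-subtracted signal crosses zero going
up: indices $i$ with $x_{i-1} < 0$ and $x_i \ge 0$ (exact zeros count as
non-negative). Each span between consecutive rising crossings is one
movement; the leading span before the first crossing and the trailing span
after the last are discarded, and spans shorter than `min_movement_s`
(default 0.05 s) are dropped as noise-induced micro-crossings. Rising
crossings were chosen so each span leads with its aperture peak, matching
the waveform morphology. The movement keeps its original sample values; the
subtracted mean is only used to find boundaries, and is stored as `mean_nm`
for padding.

The signal average "per second" admits two readings, and the choice
matters. A piecewise-constant mean over contiguous 1 s blocks
(`blockwise_mean()`) steps discontinuously at block boundaries; whenever a
downward step lands mid-cycle the detrended signal jumps from negative to
non-negative and a spurious movement boundary appears — in zero-noise
five-class sessions this fabricated one to two extra movements per few
hundred. The default is therefore a centered *running* mean of the same 1 s
width (`sliding_mean()`), which varies smoothly and yields exactly one
rising crossing per chew cycle on clean signals; the block variant remains
available via `segmentation_params(mean_type = "block")`. With the running
mean, zero-noise sessions are recovered movement for movement; under the
default noise, crossings near the jaw-closure zero passage can split cycles
into fragments, which only ever *increases* per-class movement counts and
leaves labels intact (fragments are still capped per class downstream).

A numerical footnote: the running mean is computed from a cumulative sum
*anchored at the final sample value*, so windows lying entirely inside a
constant stretch (the session tail) return that constant exactly rather
than to within cumulative-sum rounding. The terminal-crossing mechanism
depends on this exactness.

Labels are the per-sample modal label over the span, with ties broken
toward the earliest class in canonical order — per-sample truth is available
here, unlike in the field, where labels come from session context.

Padding (`pad_to_length()`) appends copies of the movement's local mean at
the tail until the 1000-sample instance length is reached; longer movements
are truncated to their first 1000 samples (only the shorter case is
published; tail-append and tail-truncate are the corresponding least-surprise
choices). Padding is idempotent.

## Feature construction

Each instance has 1030 attributes: a1–a1000 are the padded wavelength
samples, a1001–a1030 the magnitudes of the first 30 components of

$$X(k) = \frac{1}{N}\sum_{n=0}^{N-1} x(n)\, e^{-j 2\pi k n / N}.$$

Under this normalization a1001 — the DC component — equals the absolute
segment mean, and the bin spacing is $f_s/N$.

The transform is evaluated on the **unpadded** native movement
($N$ = native length), not the padded 1000-sample vector. This is the only
reading under which the published per-class bin spacings (2.49, 1.66, 2,
1.66, 1.54 Hz) are arithmetically possible — a padded $N = 1000$ at 1 kS/s
forces 1 Hz spacing for every class — and it realizes the stated
interpretation that the bin spacing represents the period of the analyzed
signal: a segment spanning one chew cycle puts bin 1 at the fundamental.
The literal fixed-$N$ alternative is preserved as
`feature_params(fft_input = "padded")`. Magnitudes (moduli) are stored, as
the published spectra are non-negative; the bin spacing travels as metadata
rather than as an attribute. Attributes stay in wavelength units (nm), which
is what the original classifier consumed; strain is for reporting.

Reduced configurations with 500 or 250 time attributes (plus the same 30
spectral attributes) are produced by uniform decimation of the padded
vector — every 2nd or 4th sample — since no reduction method is published.

`build_dataset()` takes the first `per_class_cap` (default 200) movements of
each class in temporal order, yielding the canonical 1000 × 1030 training
set for a 200-movement-per-class session.

## The C4.5 learner

The tree is induced from scratch on continuous attributes only (the
pipeline produces no categorical attributes and no missing values, so
C4.5's categorical branching and fractional-instance machinery are
deliberately omitted):

- **Impurity.** Entropy in bits, $H = -\sum_c p_c \log_2 p_c$.
- **Candidates.** Binary splits $a \le t$ / $a > t$ at midpoints between
  consecutive distinct sorted values of each attribute, requiring at least
  `min_leaf` (default 2) instances per branch and positive gain.
- **Selection.** The gain-ratio maximizer, restricted — when
  `use_average_gain_guard` is on (default) — to candidates whose gain is at
  least the mean gain of all positive-gain candidates, Quinlan's guard
  against gain ratio favoring pathologically unbalanced splits. Ties go to
  the lowest attribute index, then the lowest threshold, so induction is
  fully deterministic.
- **Stopping.** A node becomes a leaf when pure, smaller than
  `2 * min_leaf`, or splitless; the leaf class is the majority, ties toward
  the earliest class in canonical order.
- **Pruning.** Bottom-up subtree replacement using the pessimistic
  error-based criterion: with $e$ training errors among $n$ instances, the
  estimated error count is $n$ times the exact binomial upper confidence
  limit at confidence factor CF (default 0.25, the classic release
  default), i.e. the largest $p$ with $P(X \le e \mid n, p) \ge$ CF,
  computed via the beta quantile. A subtree collapses when the would-be
  leaf's estimate does not exceed the sum of its leaves' estimates (ties
  prune, favoring the simpler tree). Node counts never increase; as CF
  approaches 1 the estimates approach the observed errors and pruning tends
  to a no-op. Subtree raising is not performed.

The exhaustive midpoint scan is implemented in C++ (as the classic tree
packages do); an independent R enumeration over every (attribute, midpoint)
pair serves as the test oracle. Rules are extracted one per leaf as ordered
`IF (aK <= v) AND ... THEN class` conjunctions, so every instance satisfies
exactly one rule. Models serialize to JSON and round-trip exactly.

## Evaluation

`cross_validate()` performs stratified k-fold cross-validation (default
k = 10) with a seeded per-class round-robin assignment whose fold counter
continues across classes, so fold sizes stay balanced and k = m degenerates
to leave-one-out. Within each fold a tree is induced and pruned on the
other folds and predicts the held-out fold; pruning inside each fold is
standard practice (whether the original analysis pruned per fold or once is
unstated). The out-of-fold predictions aggregate into a single confusion
matrix whose rows sum to the per-class census — this aggregated matrix is
the reported surface, since the published matrix's rows sum to the full
per-class counts. The "best classifier" is the fold tree with the highest
held-out accuracy (ties toward the lowest fold), mirroring the stated — if
statistically informal — selection procedure.

## What the synthetic stand-in does and does not show

The generator reproduces the *published statistical structure*: five
classes, per-class peak strains and chew rates, the DC ordering, disjoint
amplitude histograms, quasi-periodic peak-then-trough cycles, and a
1000-instance balanced training set. It does not reproduce the animal: no
within-session fatigue or drift, no bolus-to-bolus correlation, no sensor
temperature sensitivity, no inter-animal variability, and the waveform is an
idealized smooth pulse rather than a measured strain profile. Passing the
pipeline's accuracy floor on synthetic data therefore demonstrates that the
*method* — segmentation, harmonic features, C4.5 with pruning — separates
classes with the published signal structure; it says nothing further about
accuracy on new in vivo recordings, and the exact published tree (83 nodes)
is not a reproduction target since it depends on the unavailable data.

On the default conditions (200 movements per class, seed 1) the aggregated
out-of-fold accuracy lands around 99 %, above the published 94 % overall
rate — unsurprising, since idealized waveforms with well-separated DC
levels are easier than real strain data, and the residual confusion sits in
the dietary-supplement/ryegrass pair, as in the published matrix.

## Numerical choices and problem sizes

- Exact zeros count as non-negative in crossing detection; attribute values
  exactly at a threshold descend left.
- Gain comparisons in the split scan use a $10^{-12}$ tolerance; the
  pruning comparison uses $10^{-9}$ on estimated error counts (ties prune).
- Degenerate inputs error early and explicitly: empty traces, empty
  segments, empty datasets, zero-total entropy, confidence factors outside
  (0, 1), sampling rates at or below twice the fundamental (aliasing).
- The test suite runs sessions of 3–40 movements per class; the acceptance
  checks run the full 200-per-class, 1000 × 1030, 10-fold configuration,
  which completes in seconds. The Monte-Carlo jitter check uses 1000
  replicate cycles.

## Known limitations

- No hysteresis in crossing detection: under heavy noise, low-amplitude
  classes (idleness especially) fragment into multiple spans per cycle.
  Fragments remain correctly labeled and never reduce class counts, but
  native lengths then underestimate the chew period for those classes.
- The `"block"` detrending variant retains the boundary-step artifact
  described above and is provided for comparison, not recommended.
- C4.5 missing-value handling, subtree raising, windowing and rule
  post-simplification are not implemented.
- The strain calibration k is an assumed constant; absolute wavelength
  thresholds in extracted rules shift linearly with it.
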