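# fbgchew

Classification of ruminant ingestive behavior from jaw-bone strain measured
by a fiber Bragg grating (FBG) sensor.

## The problem

Monitoring what and how a grazing animal chews — concentrate, hay, fresh
grass, rumination, or nothing at all — matters for nutrition, pasture
management and animal-health studies. An FBG strain gauge fixed to the
mandible turns every jaw open–close cycle into a transient in the reflected
Bragg wavelength: mechanical strain ε shifts the wavelength linearly,

    λ(t) = λ_B + k · ε(t),

with λ_B = 1541 nm and sensitivity k in pm per µm/m (default 1.2). Different
feeds load the jaw differently: peak strains of roughly 50 µm/m (dietary
supplement), 178 µm/m (hay), 100 µm/m (ryegrass), 42 µm/m (rumination) and
12 µm/m (idleness), at chew rates of 2.49, 1.66, 2.0, 1.66 and 1.54 Hz
respectively, with DC baselines ordered idleness < rumination < feeding.

`fbgchew` implements the full analysis pipeline as tested, reusable code,
with a class-conditional waveform simulator standing in for the in vivo
recordings (which are not publicly deposited):

1. **Simulation** — labeled chewing sessions as quasi-periodic strain
   waveforms (aperture peak, closure trough, jitter, sensor noise), encoded
   to Bragg wavelength (`generate_session()`, `encode_wavelength()`).
2. **Segmentation** — per-second mean detrending and rising zero-crossing
   detection delimit individual chew movements; each is padded with its
   local mean to a fixed 1000 samples (`segment_movements()`,
   `pad_to_length()`).
3. **Features** — each movement becomes a 1030-attribute instance: 1000
   padded wavelength samples plus the magnitudes of the first 30 components
   of the 1/N-normalized DFT, X(k) = (1/N) Σₙ x(n) e^(−j2πkn/N), computed on
   the unpadded movement so the bin spacing equals the chew fundamental
   (`build_instance()`, `build_dataset()`).
4. **Learning** — a from-scratch C4.5 decision tree on continuous
   attributes: entropy in bits, information gain, gain-ratio split selection
   with Quinlan's average-gain guard, midpoint thresholds, and pessimistic
   error-based post-pruning from an exact binomial upper confidence limit
   (`induce()`, `prune()`, `predict()`, `extract_rules()`).
5. **Evaluation** — stratified 10-fold cross-validation, aggregated
   out-of-fold confusion matrix, per-class and overall accuracy, and
   best-classifier selection (`cross_validate()`).

## Worked example

```r
library(fbgchew)
res <- run_pipeline(movements_per_class = 50, seed = 1)
print(res$cv)
```

```
10-fold cross-validation (seed 1)
                    predicted
truth                dietary_supplement hay ryegrass rumination idleness
  dietary_supplement                 49   0        1          0        0
  hay                                 0  50        0          0        0
  ryegrass                            0   1       49          0        0
  rumination                          0   0        0         50        0
  idleness                            0   0        0          0       50
overall accuracy: 99.2%
per-class accuracy (%): dietary_supplement=98.0, hay=100.0, ryegrass=98.0, rumination=100.0, idleness=100.0
best fold: 1 (100.0% held-out accuracy)
```

The matrix rows are true classes, columns predictions, one row sum per
simulated class; the overall accuracy is the trace over the total. The best
fold's pruned tree is small and readable:

```r
print(res$cv$best_tree)
#> C4.5 decision tree (pruned): 9 nodes = 5 leaves + 4 decision
head(extract_rules(res$cv$best_tree), 2)
#> IF (a1 <= 1541.022717) THEN idleness
#> IF (a1 > 1541.022717) AND (a1 <= 1541.042642) THEN rumination
```

Each rule is the conjunction of threshold conditions on the path to one
leaf; thresholds are in nm of Bragg wavelength. A file-driven equivalent
(`cmd_simulate()` → `cmd_featurize()` → `cmd_train_eval()`) chains the same
stages through CSV/JSON/YAML documents.

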