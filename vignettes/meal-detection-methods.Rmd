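---
title: "Meal detection from CGM response patterns: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal detection from CGM response patterns: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the detection model and its assumptions, the parameters that matter, what
the bundled simulator does and does not emulate, and the design choices
made where more than one reasonable construction exists. Function-level
detail lives in the help pages; the worked numbers live in the README and
are produced by the code shown there.

## The detection model

The working assumption is that one person's post-meal glucose excursions
recur in a small number of characteristic *shapes*, even though their
amplitude and baseline vary with context (insulin, activity, stress). Shape
is what survives z-normalization, so the whole pipeline operates on
z-normalized windows:

1. **Responses.** Every logged meal contributes the contiguous window of
   length Δ~response~ starting at the meal's grid point. Windows crossing a
   sensor gap or the end of the record are skipped — a response with a hole
   in it is not a shape.
2. **Patterns.** Responses are z-normalized and clustered by Euclidean
   distance (agglomerative, average linkage); each of the |P| clusters is
   represented by its *medoid*, the member with the smallest summed
   distance to the rest. Medoids rather than centroids keep every pattern
   an actually observed response, which matters when |P| is small and the
   clusters are uneven.
3. **Profiles.** For each pattern, the distance profile holds the
   z-normalized Euclidean distance to every subsequence of the signal,
   computed per contiguous gap-free segment with the FFT/rolling-moment
   (MASS) formulation and stitched with `Inf` sentinels at positions whose
   window crosses a gap or has zero variance. The sentinels implement the
   "exclude non-contiguous candidates" rule upstream of selection.
4. **Candidates.** Per pattern: strict local minima of the profile below
   d~cutoff~, taken greedily in ascending distance order while suppressing
   minima within Δ~valley~ of an already accepted one. Pooled across
   patterns: 1-D average-linkage clustering of candidate times, cut at the
   grouping scale, one minimum-distance representative per cluster. The
   result is a *dynamic* number of candidates — patterns that recur often
   contribute more — in contrast to the fixed top-n baseline that
   `topNSelect()` retains for comparison.
5. **Classification.** Each candidate becomes nine features (below) and a
   binary label: `Meal` iff it starts within δ~margin~ of a logged meal
   (closed interval). Six classifier types are trained; the participant's
   model is the validation-F2 winner. F2 rather than F1 because a missed
   meal (recall) is costlier than a spurious reminder (precision) in the
   intended applications.
6. **Evaluation.** Predictions are matched one-to-one to logged meals
   within δ~margin~, greedily by ascending time difference. This is the
   only matching scheme consistent with reporting both
   `tp + fp = predictions` and `tp + fn = meals`, which the package treats
   as invariants. Metrics are reported per day, pooled over a split
   (metrics of summed counts), and macro-averaged (means of per-day counts
   and of per-day metrics) — the two aggregations genuinely differ and are
   labeled.

### Features

All nine features are computable from the glucose series and the window
start alone — the event log never leaks into them: start BG (mg/dl),
forward-difference BG derivative over one grid step (mg/dl/min), hours
since local midnight, window minimum and maximum (mg/dl), minutes from the
start to each extremum, and the average slope from the start to each
extremum (mg/dl/min, defined as 0 when the extremum is the start itself;
ties take the earliest sample). The clock-time feature carries the daily
meal routine; the extremum geometry carries the response shape at its
original scale, complementing the scale-free pattern match.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| Δ~response~ | 120 | min | response window; long enough to span delayed responses, short enough to stay meal-local |
| δ~margin~ | 60 | min | labeling and evaluation tolerance; absorbs logging-time uncertainty |
| \|P\| | 3 | — | number of patterns; small values already capture the main shape families |
| d~cutoff~ | 4 | — | z-normalized distance threshold; only meaningful on that scale (max 2·sqrt(n) ≈ 9.8 for n = 24) |
| Δ~valley~ | 120 | min | minimum separation of same-pattern candidates; also the default grouping scale |

All are settable in `selectionParams()`; the grouping cut is independently
settable (`groupMinutes`) but defaults to Δ~valley~ because a single
temporal scale for "the same excursion" is the parsimonious choice.

## Numerical conventions

- **Indexing** is 1-based with inclusive windows `[i, i + n - 1]`, the
  native R convention.
- **z-normalization** uses the population standard deviation (denominator
  *n*); under it a z-normalized window has squared norm *n* and profile
  values are bounded by 2·sqrt(n). Windows with sd below 1e-8 mg/dl are
  degenerate: flagged in `znormalize()`, excluded from clustering, `Inf`
  in profiles.
- **Valley plateaus** (runs of equal profile values below both neighbors)
  contribute their leftmost index; profile ends act as high neighbors.
- **Grouping cut**: clusters merge when their average-linkage distance is
  strictly below the grouping scale, so two candidates at exactly
  Δ~valley~ — the closest the suppression step allows — are not re-merged.
- **Ties**: cluster representatives by lowest distance, then earliest
  time, then lowest pattern id; event synchronization ties to the earlier
  reading; matching ties to the earlier prediction; model-selection ties
  by F2, then F1, then a fixed classifier name order.
- **tp = 0** yields PPV = TPR = F1 = F2 = 0 (the undefined-ratio
  convention); all-zero confusion counts are an error rather than a
  silent 0/0.
- **Splitting** is by time span, not sample count: the test range is the
  final `testSpanDays`, validation the equal span before it, training the
  remainder; events travel with their timestamps on half-open boundaries.

## The classifiers

The six types are deliberately ordinary, library-default models — the
pipeline treats the classifier as a replaceable component: a boosted
ensemble of depth-1 decision stumps (discrete AdaBoost/SAMME, 50 rounds,
implemented in-package), a CART tree (`rpart`), gradient-boosted trees
(`xgboost`, 100 rounds, logistic objective), Gaussian naive Bayes
(`e1071`), a single-hidden-layer perceptron (`nnet`, 8 units, features
standardized internally since the feature scales differ by orders of
magnitude), and a random forest (`randomForest`, 500 trees). Stochastic
learners are seeded per run and each model records the hyperparameters it
used. No tuning is performed anywhere: model *selection*, not model
optimization, is the subject.

## The synthetic participant

`simulateParticipant()` emulates the statistical structure the method
relies on, not glucose physiology:

- a circadian sinusoidal baseline plus Gaussian sensor noise, clipped to
  the sensor range 40–400 mg/dl;
- additive meal responses drawn from a library of three distinct kernels
  (fast/sharp, medium with a pre-peak dip, slow/large — matching the
  default |P| = 3), each a smooth rise to a peak followed by exponential
  decay, zeroed beyond 4 h;
- a daily meal schedule (three main meals at high probability, an optional
  snack) snapped to the 5-minute grid;
- *non-meal disturbances*: smooth 20–45 mg/dl excursions over 40–90 min at
  about one per day, present in the signal but in neither event log. These
  stand in for the exercise/stress effects that make meal detection
  nontrivial; without them a clean simulation has no negative examples and
  the classification problem collapses;
- sensor gaps as geometric-length runs (mean 6 samples) rather than
  i.i.d. holes, to exercise the contiguity rules realistically;
- an imperfect log: each true meal is dropped with `missLogProb` and
  logged timestamps are jittered (sd 5 min by default).

What it does **not** emulate: insulin dynamics and meal–insulin coupling,
carbohydrate-dependent response magnitude, overlapping responses from
closely spaced meals beyond simple addition, sensor drift/compression
artifacts, or behaviorally correlated logging errors. Green tests on the
simulator therefore demonstrate that the machinery is correct and that the
method recovers recurring shapes under noise, gaps and imperfect logs — not
that any particular accuracy will be reached on clinical data.

Default problem sizes were chosen to make a thorough run cheap: the
end-to-end checks use a 28-day participant (8,064 grid samples, roughly 90
meals) split 14/7/7 days, and the profile oracle comparison uses 100 random
series of 60–150 samples. A full train-plus-detect cycle at these sizes
takes a few seconds.

## Design choices on genuinely open points

- **Pattern clustering**: average-linkage agglomerative clustering with
  medoid representatives, both configurable in principle; chosen so that
  patterns remain observed responses and the procedure is deterministic
  given input order.
- **Matching protocol**: greedy nearest-first one-to-one matching (see
  above for why one-to-one is forced by the count identities).
- **Augmentation**: the training positives include each logged meal that
  is matched by at least one `Meal` candidate, featurized at the meal's
  own synchronized grid index — keeping the ground truth in the training
  set; *dangling* meals (matched by no candidate) contribute nothing,
  since the classifier only ever sees candidates.
- **Per-day evaluation** treats days independently after partitioning at
  local midnight; a prediction near midnight cannot match a meal on the
  neighboring day. This is a convention, stated rather than hidden.
- **Boosting variant**: discrete AdaBoost over stumps is implemented in
  the package itself; it is the textbook algorithm and keeps the
  six-classifier roster intact.

## Known limitations

- Patterns are fixed-length and uniformly z-normalized; responses that
  differ mainly in duration or amplitude map to the same shape.
- The selection stage is offline (whole-split): Δ~valley~ suppression and
  global grouping look ahead in time, so the pipeline as implemented is
  not a streaming detector.
- Labels inherit every defect of the self-reported log; the degraded-log
  run in `scripts/acceptance.R` quantifies the precision cost of missing
  entries, but systematic (non-random) misreporting is untested.
- With very few logged meals the pattern stage fails by design (fewer
  non-degenerate responses than |P|); the error suggests lowering |P|.
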