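---
title: "Two-stage SVB/VB heartbeat classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SVB/VB heartbeat classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbclass)
```

## The problem and the model

Long-term ambulatory ECG produces on the order of a hundred thousand
heartbeats per day. Clinically, the binary pre-classification of every beat
into *supraventricular origin* (SVB: sinus beats including bundle branch
blocks, plus supraventricular ectopics — AAMI classes N and S) versus
*ventricular origin* (VB: ventricular ectopics and fusion beats — classes V
and F) separates beats of normal, narrow morphology from the dangerous wide
ventricular ones, and is the foundation for ventricular-ectopy counting and
alarm logic in monitoring devices.

`hbclass` implements a two-stage design aimed at real-time use:

* **Stage 1** is a cheap waveform preprocessor. It learns the patient's
  *predominant (reference) beat template* in the first 10 s, then matches
  every subsequent beat against it by a single correlation coefficient.
  Beats that match are immediately assigned to SVB — in sinus-dominated
  recordings this fast path absorbs the overwhelming majority of beats.
* **Stage 2** is a trainable classifier that sees only the non-matched
  residue. For those beats 20 time-domain features are measured and
  expanded to 210 second-order terms, and one of four models — k-means
  cluster, empirical-percentile fuzzy, linear discriminant, or a
  classification tree — takes the SVB/VB decision. The decision for a beat
  is delayed until the following beat has arrived, because the feature set
  includes the next beat's template-match code, correlation and RR interval.

### Preprocessing

Records are resampled (piecewise-linearly) to 250 Hz and band-passed to
0.05–75 Hz. Two composite leads are derived from the two channels:

* magnitude `mag[i] = sqrt(lead1[i]^2 + lead2[i]^2)` (mV), and
* velocity `vel[i] = sqrt(d.lead1[i]^2 + d.lead2[i]^2)` with `d` the
  first-order sample difference (`vel[1] = 0` by convention).

Both are nonnegative, which matters below: the template correlation of two
velocity windows always lies in [0, 100] %.

The band names only a passband, so the realization is a package choice: a
2nd-order Butterworth high-pass at 0.05 Hz cascaded with a 4th-order
low-pass at 75 Hz, each applied forward–backward for zero phase (through
the `signal` package). The 0.05 Hz edge settles over tens of seconds;
tests therefore evaluate the DC response in the interior of a 60 s signal.

### Stage 1: template matching under an adaptive threshold

The beat analysis window is the 180 ms (45 samples) of `vel` and `mag`
following the QRS onset. QRS boundaries are delineated from the smoothed
velocity (onset: last pre-fiducial sample below 10% of the beat's peak
velocity for at least 20 ms, searched 150 ms back; offset symmetric,
300 ms forward). The correlation of a beat window `B` against a template
window `T` is

    corr = 100 * sum(B*T) / sqrt(sum(B^2) * sum(T^2))  (%)

A beat matches when `corr >= ACT`, the *adaptive correlation threshold*,
bounded to [80, 98] % and updated once per non-overlapping 10 s segment:

    ACT(i) = 0.75 ACT(i-1) + 0.25 OCT(i-1)

where the *optimal correlation threshold* OCT of a segment is the highest
value in {98, 97.5, …, 80} at which at least 75% of the segment's beats
correlate at or above the threshold with at least 25% of the other beats
(the "basic rule"; the 25% condition is evaluated per beat). The ACT is a
first-order low-pass of OCT: with constant OCT = c it converges to c
geometrically (`|ACT(i) - c| = 0.75^i |ACT(0) - c|`), which the test suite
asserts.

During the learning period the beats of the first 10 s are greedily grouped
by morphology (a beat joins the first subgroup whose running average it
correlates with at or above the segment's OCT, else founds a new one). The
predominant subgroup is the "largest with the shortest QRS": we score each
subgroup by `0.7 * members/max_members + 0.3 * (1 - dur/max_dur)`. The
weights are a package choice — size must dominate so the sustained rhythm
wins, while the duration term breaks size ties toward narrow (sinus)
morphology; both are arguments of `learn_reference()`.

A bank of up to 8 templates is maintained: a reference match updates the
reference by an exponential running average with new-beat weight 1/8
(standard ECG averaging practice; the matched-template fixed point is
tested), a non-reference match updates that template, and an unmatched
beat founds a new template only while the bank is below its cap — there is
no replacement policy. Beats matching a *non-reference* template still go
to Stage 2 and count as "non-matched to the predominant template" in
Stage-1 scoring.

Learning-period beats are replayed against the learned bank (without
updating it) for their own decision and use the learning-period default
reference features; this choice keeps every scored beat decided exactly
once while leaving the streaming state untouched.

### The 20 basic features and the 210-column expansion

F1–F3 are ternary template-match codes of the current/previous/next beat
(reference = 0, other template = 1, none = −1); F4–F5 binary P-wave flags
of the beat and the reference; F6–F8 correlations (%) of the
current/previous/next beat against the reference; F9–F11 QRS duration (ms)
of beat, reference and difference; F12–F14 QRS activity
(`100*mean(mag)/max(mag)`, %); F15–F17 QRS mobility
(`100*sum(vel)/sum(mag)`, a time-domain high/low frequency-content ratio,
%); F18–F19 the current/next RR interval normalised to the mean of the
last four RR intervals (%); F20 the relative RR variability of the
trailing 10 s. "Reference RR variability" is not pinned down by a formula
anywhere, so the package commits to the mean absolute successive RR
difference over the trailing 10 s, normalised to the mean RR.

During learning (no reference template) the reference-side defaults are:
P wave present, corr 80%, QRSdur 100 ms, QRSact 100%, QRSmob 100%; missing
neighbours at record edges take the same defaults.

The expansion appends all 190 pairwise products `Fi*Fj` (`i < j`,
lexicographic order, no squares): 20 + 190 = 210 columns, in a frozen,
regression-tested order (`expanded_feature_names()`). Squares are excluded
precisely so the count is 210; the discrete×continuous products are
included (they are among the best-ranked interactions, e.g. `F6xF18`).

### Stage 2: the four classifiers

All four operate on a selected subset of the 210 columns and predict
SVB/VB. Deliberate tie-break conventions, chosen once and documented, are:
fuzzy and cluster label ties resolve to VB (favouring ventricular
sensitivity), the LDA equality case resolves to class 2 (VB), and the tree
split search resolves to the lowest feature index, then lowest threshold.

**Cluster.** k-means (Lloyd, Euclidean distance) from k random distinct
rows, 10 restarts, 100-iteration cap, emptied clusters re-seeded to the
farthest row. Each cluster is labelled by its majority class; prediction is
the label of the nearest centroid. The kept restart maximises the
*training* criterion Mean(Se,PPV) (then Se) rather than within-cluster
variance — the clustering is only a vehicle for the classifier.

**Fuzzy.** Per feature and class, the empirical distribution of the
training values is the membership model. The confidence of value `x` for
class `c` is `1 - |2 F_c(x) - 1|` with `F_c` the class ECDF under the
midpoint convention at ties — maximal (1) at the class median, 0 outside
the class range. This folded-percentile form is one defensible reading of
"percentile ranking"; it is symmetric, parameter-free and robust to
outliers. Prediction averages confidences over the selected features and
takes the larger class.

**LDA.** Pooled-covariance discriminant:
`a = S^-1 (mu1 - mu2)`, `S = ((n1-1)S1 + (n2-1)S2)/(n1+n2-2)`, assign
class 1 (SVB) iff `(y - (mu1+mu2)/2)' a > ln(pi2/pi1)`. Standardized
coefficients (a scaled by pooled standard deviations) and the apparent
error rate APER = (N − n11 − n22)/N are reported. A reciprocal condition
estimate of `S` below 1e-12 raises a typed conditioning error, which the
stepwise trainer uses to exclude the offending feature permanently.

**Classification tree.** Exhaustive univariate splits at midpoints between
adjacent distinct values; descent is strictly-less-than. Impurities use the
natural logarithm: deviance `2n(-sum p log p)` (= 2n × entropy, so the two
criteria choose identical splits), Gini `1 - sum p^2 = 2p1(1-p1)` for two
classes, and the twoing index `(pL pR/4)(sum_j |p_jL - p_jR|)^2` evaluated
on splits. Class priors reweight the class counts to the prior ratio at
every node (the node's effective proportions equal the priors), which is
how "priors affect the relative proportions" is operationalised; they act
in growth only, while pruning costs use raw training proportions. Growth
stops at purity, at impure nodes smaller than `min_impure` (default 10),
or when no candidate threshold exists; zero-gain splits are allowed (with
the deterministic tie-break), which is what lets the tree cut through
XOR-like interaction structure whose first cut is locally uninformative.
Pruning iteratively collapses the internal node with the minimal increase
in resubstitution misclassification cost, recording the full sequence;
"decision nodes" counts internal (split) nodes, so pruning to 1 leaves a
single split and to 0 a majority stump. The split search and the Lloyd
iterations are small C++ kernels (the same place the field's tree and
clustering code keeps its inner loops).

### Training protocol

The criterion is Mean(Se,PPV) = (Se + PPV)/2 (%), with Se = TP/(TP+FN)
and PPV = TP/(TP+FP) computed for the VB class on the training rows —
weighting SVB false positives and VB false negatives equally under heavy
class imbalance. Forward stepwise selection adds, at each step, the
feature whose addition maximises the criterion (ties: higher Se, then
lower column index — the last tie-break is a package choice for
determinism) and stops when the best candidate raises neither the
criterion nor, at an equal criterion, Se. The step cap defaults to 150.
The cluster-count sweep covers k = 2…10 (rule of thumb
`floor(sqrt(210/2)) = 10`); the prior sweep evaluates a grid of
(SVB, VB) priors and prefers the first pair with Se > PPV whose criterion
is within 0.5 points of the grid maximum ("Se above PPV but no
deteriorated criterion", operationalised). The tree does not use stepwise
selection — it self-selects features during growth — and is tuned by the
prior sweep and the pruning scan instead.

### Evaluation accounting

Stage-1 scoring: TN/FP are the matched/non-matched N+S beats, TP/FN the
non-matched/matched V+F beats. Combined scoring pools the Stage-1 SVB
fast-track with the Stage-2 decisions. The V-only figures drop F beats
entirely (they are hybrids, and published studies usually report V-beat
sensitivity), restricting positives to beats annotated V. Q beats pass
through the classifier but are excluded from every count. A metric with a
zero denominator is reported as undefined (`NA`), never as 0 or 100.
Because a VB beat matched by Stage 1 never reaches Stage 2, the combined
false negatives are bounded below by the Stage-1 false negatives — the
fast path caps the achievable sensitivity, which the property suite
asserts.

## The synthetic data

Two generators make the package self-contained and its tests exact.

`gen_ecg_stream()` builds an annotated two-lead stream from Gaussian
bumps: normal beats are narrow (90 ms QRS) with a P wave 160 ms before the
R peak and an upright T; PVCs are wide (160 ms), P-free, with inverted
polarity on one lead, planted at `prematurity` (default 0.7) of the RR
interval with a compensatory pause. PVCs are never placed in the first
10 s (so the learning period stays sinus, as it is in the vast majority of
recordings) and never adjacent. Defaults: 75 bpm, 1 mV R amplitude,
0.15 mV P — ordinary adult sinus values. What it does *not* emulate:
baseline wander, respiration, electrode artefacts, morphology drift,
polymorphic ectopy, or atrial fibrillation; a pass on this generator
demonstrates the mechanics of the two-stage pipeline (template learning,
fast-track, PVC routing), not database-grade performance.

Because the stream generator's beat morphologies are idealised, the
feature distributions it induces differ from the corpus-level table below
(its PVCs correlate more strongly with the reference template than real
ventricular beats do). End-to-end record demonstrations therefore train
their Stage-2 model on features extracted from an independent synthetic
*training record* (`run_two_stage(..., model = NULL)` runs Stage 1 and
feature extraction only), generated with a small additive noise
(0.03 mV RMS) so that template matching operates realistically; models
trained on the corpus-level table are exercised on held-out tables from
the same generator.

`gen_feature_table()` draws Stage-2 feature tables directly from the
class-conditional distributions observed at the input of Stage 2 in the
multi-database training corpus: categorical frequencies for F1–F5 and
Gaussian mean ± std for F6–F20 per class (e.g. curRR 100.1 ± 12.8 % for
SVB vs 73.1 ± 16.4 % for VB), with correlation-type features clipped to
[0, 100] and an optional Gaussian-copula correlation for the (F6, F18)
pair — that interaction is the first feature every classifier selects.
Features are otherwise drawn independently per class because no
covariances are reported for the corpus; real feature tables are
correlated, so held-out accuracies on this generator are optimistic and
are read as a qualitative "all four models solve the task" check, not as a
database result.

## Problem sizes and numerical choices

The package's own verification runs use: 5000 beats per class for the
feature-table experiments (training and an independently seeded held-out
table of the same size), stepwise selection to 8 steps for the fuzzy and
LDA models and 5 steps for the cluster model (their criterion plateaus
within a handful of features on this synthetic table; the tree
self-selects and is grown to purity under `min_impure = 10`), k = 9
clusters with 10 restarts, LDA
priors 30/70 (SVB/VB) and tree priors 50/50 — the settings found best in
the original tuning sweeps. Floating-point tie handling uses an absolute
tolerance of 1e-9 in the trainer and 1e-12 in the split search; the
conditioning threshold for the pooled covariance is rcond < 1e-12.
Degenerate inputs are defined, not special-cased ad hoc: zero-energy beat
windows correlate 0 (with a warning), all-zero magnitude windows give
QRSact = QRSmob = 0, a flat signal delineates to the two-sample fallback
around the fiducial, and segments with fewer than two beats inherit the
previous OCT (initially 90).

## Known limitations

* The QRS detector is out of scope: annotation fiducials (taken as R-peak
  positions) drive the pipeline by default, with a pluggable detector hook
  paired to annotations within 150 ms.
* WFDB support covers text headers with format-16 signals plus a
  plain-text TSV annotation dialect — enough for fixtures and interchange,
  not a general PhysioNet reader.
* Multi-class (N,S,V,F) output, episode-level EC57 statistics, template
  replacement policies and >2-lead records are not implemented.
* Stage-2 training metrics are resubstitution metrics on the training
  table; validation is a single held-out table, not cross-validation.
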