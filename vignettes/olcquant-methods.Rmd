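---
title: "Methods and design choices in olcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in olcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

olcquant packages the quantification layer of an intravital zebrafish
imaging workflow around oligodendrocyte lineage cells (OLCs), including the
sensory-associated population that migrates to DRG sensory axons after
contacting the dorsal root entry zone (DREZ). This vignette explains what
each procedure computes, which choices were genuinely open and how we made
them, and what validation on the synthetic generators does and does not
establish about real data.

## Coordinate and unit conventions

All interfaces use the lateral imaging view: x grows anterior to posterior,
y grows ventral to dorsal, distances in micrometres. Track time is minutes
(frames are typically 5 min apart), fluorescence and behavior time is
seconds, and DREZ-contact delays are reported in hours, matching how such
delays are usually quoted. Pixel coordinates are 0-based `(row, col)` at
pixel centers.

## Migration features

`path_length()` is the sum of Euclidean steps between consecutive tracked
centroids; `velocity()` divides it by elapsed time; `net_displacement()` is
the start-to-end chord, so `path_length >= net_displacement` always (the
triangle inequality), with equality only for straight monotone runs.

"Direction change" has no universal definition in manual tracking studies;
counts could come from a turning-angle criterion, a quadrant rule or pure
visual judgment. We adopt an explicit, parameter-transparent operator:

* consecutive displacement vectors shorter than `min_step` (default 2 μm,
  about the jitter of manually traced centroids) are merged forward, so
  sub-resolution wiggle never scores;
* a direction change is a turning angle **at or above** `angle_threshold`
  (default 90°) between successive retained vectors. The threshold is
  inclusive so that the default scores right-angle turns, the natural
  reading of "changed direction" for a cell that was heading dorsally and
  leaves at a right angle.

Both parameters are exposed everywhere the operator is used. The count is
invariant under rotation, translation, and re-timestamping, and under
uniform scaling when `min_step` is scaled alongside the track.

`contact_delay()` converts the two visually scored annotations (pioneer
axon entry, first DREZ contact) to an hour-valued delay and refuses
negative delays as data errors. `dorsal_displacement_after_contact()` reads
the dorsoventral coordinate at the first sample at or after the annotated
contact, so it is well defined on discretely sampled tracks.

## Clustering migration profiles

Clustering operates in the 2-D feature space (total distance, direction
changes) in which the migration profiles were originally described.
Distances span hundreds of micrometres while change counts stay below ten,
so raw Euclidean k-means would cluster on distance alone. Whether the
original analysis standardized features is unknowable from the text; we
**z-standardize by default** and keep `standardize = FALSE` to reproduce
the unscaled behavior. Centroids are always reported in original units.

The fit is Lloyd's algorithm (via `stats::kmeans`) seeded k-means++-style,
best of 20 restarts by WCSS, deterministic given `(seed, n_restarts)`, both
recorded in the result. When k reaches the number of *distinct* feature
points — routine for zero-noise synthetic data — the exact optimum (each
distinct point its own centroid, WCSS 0) is returned directly rather than
erroring; only `k > n` is an error.

The elbow method is automated as the k maximizing the second difference of
the WCSS curve over `k = 1..k_max` (default 8), i.e. the discrete curvature
of the curve; ties go to the smallest k, and the full curve is returned so
the selection can be audited. On convex WCSS curves this picks the same k a
reader would call the visual elbow, and it is deterministic. A consequence
worth knowing: k = 1 and k = `k_max` can never be selected, so `k_max`
should comfortably exceed the plausible cluster count.

`cluster_agreement()` (adjusted Rand index, delegated to
`mclust::adjustedRandIndex` and cross-checked in the tests against the
contingency-table formula) is the validation metric for label recovery.

## ROI integrated density

Polygon ROIs are filled by the even-odd rule over pixel centers; polyline
ROIs (the "trace a projection" style) include every pixel whose center lies
within half the line width of the path, inclusive. There is no sub-pixel
interpolation: masks are bit-reproducible, which we value over marginal
accuracy at these ROI sizes. Integrated density is the masked pixel sum per
frame, making it additive over disjoint ROIs and linear in intensity — two
properties the tests enforce.

Background normalization is stated in imaging methods sections far more
often than it is defined. We provide both plausible operators and default
to **subtraction**: `raw − mean(background) × roi_area`, which preserves
integrated-density units and maps a frame identical to its background to
exactly 0; `"divide"` gives the ratio to the background mean instead.

## Calcium event calling

`zscore_trace()` standardizes a trace against its own whole-trace mean and
**sample** standard deviation (divisor n − 1, the default of spreadsheet
`STDEV`-style workflows this computation descends from). A whole-trace
reference is the stated procedure; a pre-stimulus `baseline_window` mode is
provided for evoked protocols. Zero-variance traces cannot be standardized;
they return all-zero z-series flagged `degenerate` and yield zero events —
a constant cell is biologically "inactive", not an error.

`call_events()` marks samples with `z ≥ threshold` (default 2, inclusive:
exactly 2 scores) and counts one "peak" per maximal supra-threshold run;
whether published "peaks above threshold" were counted per sample or per
run is not stated, and run-based counting is the only choice that does not
scale with sampling rate. Runs separated by fewer than `min_gap_samples`
sub-threshold samples merge (default 1 = never). Events are assigned to
pre/post stimulus epochs by the time of their peak sample; a stimulus
recorded before the trace start simply puts all events in the post epoch.

Because Z-scores are scale-free, event calls are invariant under positive
affine rescaling of the raw trace — enforced as a test invariant.

**Known limitation.** The binary `z ≥ 2` activity rule has poor specificity
on featureless traces: among ~60 standardized iid Gaussian samples, about
2.3% exceed 2, so an event-free trace yields on the order of one spurious
threshold run, and the maximum of the series almost always crosses 2. On
real recordings the rule behaves better because baselines are temporally
correlated and genuinely active traces have their sd dominated by
transients — but on our white-noise synthetic baselines "percent active"
saturates regardless of the true activity rate. We report what the rule
computes rather than adjusting the noise model or threshold to flatter it;
sensitivity (≥ 6× noise transients are essentially always recovered) is the
property the generator can meaningfully certify.

## Sheath morphometry

Group comparisons use the **cell as the unit of analysis**: sheath
measurements are averaged per cell before a Welch (unequal-variance) two
sample t test across cells, because cohort sizes are quoted in cells and
per-cell "average process length" is the published quantity; pooled raw
sheaths are available behind `unit = "sheath"`. Welch rather than pooled t
because nothing in the source licenses an equal-variance assumption.

Per-fish stability across days is tested by one-way ANOVA of measurement
against day, per fish. The exact test behind published per-fish day
comparisons is not determinable (repeated-measures or corrected variants
are possible); one-way ANOVA is documented as an approximation. The fully
degenerate case (all values identical) reports `F = 0, p = 1` with a
`degenerate` flag — "no detectable change" — instead of the undefined 0/0
ratio. Under the generator's equal-day-means null the p-values are
uniform, which the suite checks with a Kolmogorov–Smirnov test.

## Behavior

Recordings longer than the 20 s assay window are truncated to their first
20 s ("normalized to 20 s"; for a fraction-of-time score, truncating the
series and rescaling the denominator are algebraically the same choice, and
truncation keeps the mask interpretable). Shorter recordings pass with a
warning and are scored over their own duration.

The original scoring of shivering was visual, so a detector had to be
designed: high-pass the displacement signal (2nd-order zero-phase
Butterworth, cutoff 5 Hz, separating shiver twitching from slow swimming
undulation), take a centered 0.5 s sliding-window RMS with partial windows
at the edges, and mark samples at or above `amp_threshold`. The default
threshold 0.5 is matched to a unit-amplitude burst: it is the RMS halfway
in *power* between silence and a full burst, which makes the marking of
burst edges unbiased (the smearing into and out of the burst cancels), so
recovered fractions track the truth to well under the 0.05 tolerance used
in validation. All three parameters are exposed; the threshold has no
published analogue and is calibrated against the generator only.

Tactile response rates are plain per-group responder percentages.

## Synthetic generators: what they emulate, and what they do not

Every generator is seeded, with all randomness flowing from the per-call
seed (no global state), and returns ground truth sufficient for
sensitivity/specificity scoring.

* **Tracks** are polylines with exactly the target total length and exactly
  the target number of 135° turns at evenly spaced vertices, plus isotropic
  Gaussian positional noise — so zero-noise features match the targets
  exactly. The default cohort (7 cells in each of three clusters at
  (85 μm, 1), (70 μm, 5) and (260 μm, 4), noise sd 2 μm, 9 frames at
  5 min) realizes the three documented migration profiles (short/direct,
  short/meandering with 3–5 turns, long-range 165–350 μm). Within those
  ranges the centers were placed so the standardized cluster geometry is
  near-equilateral — the population is genuinely three-cluster rather than
  an artifact of scaling — and the ~10–30 μm legs keep angle noise
  (sd ≈ 25°) well clear of the 90° threshold. Real tracks have hundreds of
  5-min samples with much finer steps; the generator works at the coarser
  granularity of displacement legs between turns, which is what the
  featurizer consumes after jitter merging. Positional noise scales are set
  for testability — measurement noise was never published.
* **Calcium traces** are baseline + iid Gaussian noise + instantaneous-rise
  exponential-decay transients (amplitude default 6× noise sd, decay 3
  samples, 60 samples at 2 s). Real GCaMP baselines drift and are
  autocorrelated; see the specificity caveat above.
* **Image stacks** are Gaussian blobs on constant background with optional
  pixel noise; truth is the noiseless masked sum, computed analytically
  from the rendered blob. Stored as 16-bit grayscale multi-frame TIFF.
* **Sheath tables** draw cell means at the published cohort magnitudes
  (length 187.78 vs 94.67 μm, width 5.01 vs 7.49 μm; between-cell sd =
  SEM × √n) with equal day means, one cell per fish, 3 sheaths per day over
  3–6 dpf — a calibrated null for the stability test.
* **Behavior traces** are 15 Hz unit tone bursts inside declared intervals
  over Gaussian noise at 60 Hz sampling; the frequency separation from the
  noise floor is what makes detection tunable. Group fractions default to
  the published 57.5 / 53.75 / 2.5% at n = 8 per group.

Passing the validation suite therefore shows that the operators implement
their definitions exactly and behave correctly on data with the assumed
statistical structure; it does not certify performance on real movies,
where tracking error is not isotropic white noise, fluorescence baselines
drift, and shiver bouts are neither pure tones nor cleanly delimited.

## Problem sizes and numerical choices

The validation suite and the acceptance script run at the cohort sizes the
analyses are designed for: 21-track cohorts (100 regenerated replicates for
elbow/ARI stability), 100 traces per operating-characteristic estimate,
200 simulated fish for the null-calibration check, 50 noiseless behavior
traces, and ≥ 200 random instances per brute-force oracle comparison.
Floating-point policy: turning-angle cosines are clamped to [−1, 1] before
`acos`; z-series must be finite; WCSS curves are compared with a 1e-8
slack; the z standardization contract is asserted to 1e-9. Ties are broken
deterministically everywhere (smallest k at elbow ties, first sample at
equal peak z, first-listed group order in summaries).
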