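---
title: "Methods: the robotic-replica binary-choice assay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the robotic-replica binary-choice assay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roboshoal)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter and
why they default to the values they do, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
underlying protocol leaves the design open.

## The assay and its coordinate conventions

A focal fish swims in the 54 cm central compartment of a
74 × 30 × 30 cm tank (water depth 15 cm); the stimulus — a robotic fish
replica on a rod — occupies one of the two 10 cm lateral compartments
behind transparent partitions. The origin sits at the left-front corner at
the water surface, with `z` increasing downward, so depths read directly
as "cm below the water surface" (the mid-water plane of the planar control
condition is `z = 7.5`). The central compartment is divided into three
18 cm sections along the length, classified *relative to the stimulus
side* (`near`, `middle`, `far`), and the water column into three 5 cm
levels (`top`, `middle`, `bottom`).

Section and level boundaries use half-open intervals with the last
interval closed. The protocol does not say how frames exactly on a virtual
boundary were counted; the half-open rule is a deterministic,
partition-complete choice of this package, not a claim about the original
software. Positions overshooting a wall by at most 0.5 cm — ordinary
centroid noise — are clamped; larger violations raise an error, since they
signal tracking failure rather than noise.

## The synthetic fish

`simulate_fish()` is a mode-switching random walk: a baseline `cruise`
mode alternating with four event modes taken from the described repertoire
of isolated zebrafish — `freezing`, `thrashing` against the partition,
`erratic` darts and `diving` excursions. Dwell times are exponential
(mean `1/rate`; defaults: cruise 8 s, freezing 3 s, thrashing 2 s,
erratic 2 s, diving 3 s), per-frame speeds are truncated Gaussians per
mode, and the heading diffuses with a mode-specific scale. Walls reflect
the step, preserving its length, so the raw per-frame speed equals the
drawn speed exactly; a 2 cm soft repulsion steers the heading inward
before reflection.

Defaults encode the stated world where the protocol states one: frame
rate 30 fps, cruise speed 1.69 cm/s (the replica program's average speed),
body length 3 cm. The event-mode magnitudes (thrashing 4 cm/s with violent
heading reversals at the partition, erratic 6 cm/s with strong turning,
diving as a forced down-then-up pitch across the bout) are *assumptions*:
the source protocol describes the repertoire only verbally. They are
plain parameters of `locomotion_params()`, chosen once at magnitudes a
zebrafish researcher would call plausible, and never tuned against test
outcomes. The generator is deliberately autonomous — there is no
fish → stimulus feedback, matching the open-loop robotic platform — so
study-level transfer entropy on simulated trials is null by construction;
`simulate_coupled_pair()` provides the positive control with known
directional coupling instead.

What a green test therefore establishes: that the pipeline's machinery
(tracking, metrics, information flow, statistics) is correct on data with
the assay's geometry, sampling and rough kinematics. What it does not
establish: anything about live-fish behaviour — the generator has no
hydrodynamics, no body deformation, no social response, and its
event-mode dynamics are invented magnitudes.

## The replica program

`make_replica_program()` mirrors how the robot was programmed: a donor
trajectory is downsampled to waypoints every 2.5 s and the commanded
motion is reconstructed between them. Interpolation is piecewise-linear in
each axis — the protocol does not state the motion profile between sampled
points, and linear is the minimal assumption (users substituting a real
motor profile should know the program speed is therefore a lower bound:
straightening the path between waypoints makes the program slower than its
donor, e.g. 1.42 cm/s from a 1.69 cm/s donor in the worked example).

The body-oscillation heading is `45° + 5° sin(2π·2t)` when the replica
moves toward increasing `y` and `135° + 5° sin(2π·2t)` otherwise: mean
45°/135°, 2 Hz, 10° peak-to-peak. Note one sampling subtlety: a 30 fps
grid places 15 samples per 2 Hz cycle and never hits the sine extrema, so
the *sampled* peak-to-peak span is 2 × 5 × sin(96°) ≈ 9.945°, not 10°; the
continuous signal's span is exactly 10°. `project_rm2d()` produces the
planar-control program by fixing `z = 7.5` cm and touching nothing else.

## Tracking and 3D reconstruction

The tracking chain assumes static orthogonal cameras and a planar
pixel-to-cm scale per axis (supplied from tank landmarks); lens
calibration is out of scope. Choices made where the protocol says only
"simple background subtraction" and "a multi-target tracking algorithm":

- background = pixel-wise median over ≤ 50 uniformly spaced frames
  (exact whenever a target covers a pixel in under half the frames);
- detection = thresholded absolute difference, 8-connected components,
  intensity-weighted centroids, area-descending order;
- linking = greedy nearest-neighbour with linear gap interpolation up to
  15 frames (longer gaps stay flagged invalid) — adequate for 1–2
  well-separated targets, with ambiguity messages when extra blobs appear;
- smoothing = the protocol's 18-frame moving average. An even-length flat
  window cannot be centred, so the package uses the standard centred
  even-order kernel (length 19 with half-weight ends), which passes linear
  ramps through unchanged; edges shrink and renormalize the kernel,
  preserving series length without fabricating data;
- synchronization = the lag maximizing the normalized cross-correlation
  of the two views' shared x-coordinate (±60 frame search), a software
  analogue of the replica-only alignment trial;
- fusion = x, y from the top view and z from the front view; the front
  view's x is kept only as a QC consistency check (RMS discrepancy).

Smoothing is applied per view before fusion, following the order the
tracking description implies; occlusions appear as interpolated, flagged
gaps. End to end on rendered fixtures at 3 px/cm the chain recovers
ground-truth trajectories with ≈ 0.05 cm RMSE — the 0.5 cm acceptance
bound is conservative.

## Behavioral metrics

Velocity is the first difference times the frame rate, smoothed with the
18-frame window; speed is its Euclidean norm; acceleration is the norm of
the first difference of the smoothed velocity. One bias is inherent to
this estimator and worth knowing: a moving average attenuates a rotating
velocity vector by its filter gain, e.g. 1.5% for a 1 rad/s turn at
30 fps, so curvilinear speeds read slightly low. The tests assert the
exact closed form including that gain rather than pretending the bias
away.

Time budgets classify every analysed frame (after the 600 s habituation
cutoff) into sections and levels and multiply by the frame period; both
axes conserve total time exactly. Preference indices are
`T_a / (T_a + T_b)` with `NA` (excluded, logged) when both times are zero.
Shoaling time counts frames within 12 cm (four body lengths) of the
stimulus in full 3D, including across the partition; in the Control
condition the caller passes the moving-replica program as a virtual
stimulus. Invalid/interpolated frames stay in the metrics but their
fraction is QC-reported, with a warning above 10% — the protocol is silent
on dropout handling, so exclusion would be an invention.

## Transfer entropy

Both animals' width coordinates (`y`, the axis the partition does not
constrain) are the input signals. The chain per trial: wavelet denoising,
near-section gating into maximal runs of ≥ 175 samples, 10-bin
discretization over the full 0–30 cm width (3 cm bins ≈ one body length),
the order-1 plug-in estimator in both directions, and division of each
raw estimate (bits) by its segment length — the most literal reading of
per-segment length normalization, and separable via `normalize_te()` if a
user wants raw bits.

Numerical choices:

- probabilities are maximum-likelihood frequencies with no pseudocounts,
  matching the plug-in form; unobserved triples contribute zero, and the
  estimate is non-negative up to rounding;
- the wavelet filter is a periodized Daubechies-4 pyramid, 3 levels, soft
  universal threshold with the noise scale from the finest detail MAD.
  No wavelet family or depth is stated by the protocol; these are the
  standard denoising defaults, exposed rather than hidden. (No R wavelet
  package is available in the build environment, so the pyramid is
  implemented here and tested against its reconstruction identities.)
- Markov order is fixed at 1, as the underlying model states; there is no
  embedding search;
- denoising is applied after tracking-level smoothing and before
  discretization, with a flag to disable — whether the original analysis
  fed raw, smoothed or wavelet-filtered positions to the estimator is not
  recoverable from the text.

The plug-in estimator is positively biased at finite length, and
`shuffle_null()` is this package's bias control. Its default surrogate is
a **random circular time shift** (≥ 20-sample margin) of the source
series rather than a full permutation: positional series are strongly
autocorrelated, and permutation whitens the source, mis-calibrating the
95% band in either direction depending on length (empirically 67–83%
coverage for truly independent pairs, versus 91–94% for rotation
surrogates, which also retain full power at coupling strength 0.8).
Plain permutation remains available as `method = "permute"`.

For the direction analysis, the segment identifier is the ordinal of the
near-section visit within a trial: the same replica program drives every
trial, so the k-th visit is comparable across subjects and serves as the
within-group factor. The "repeated measures" direction test is
implemented as a two-factor fixed-effects ANOVA (direction × segment,
Type-II sums of squares, single pooled error stratum): that structure —
not a subject-stratified decomposition — reproduces the degrees-of-freedom
bookkeeping of the published direction tests (numerator df 1 for
direction, one shared error df). Transfer entropy is computed only for
conditions with a moving (possibly virtual) stimulus; a static replica has
a constant width coordinate and the estimator degenerates.

## The statistical battery

Outlier screening applies the 1.5 × IQR fence (type-7 quartiles; both
configurable — the protocol names only "the interquartile range") per
condition to the time spent in each lateral section, and a flagged fish is
discarded from *all* observables, reproducing the "consistently
discarded" bookkeeping: 10 fish per condition minus the stated exclusions
yields t-test dfs (8, 7, 6, 8, 9) and the between-condition ANOVA df
(4, 38).

Preference t-tests default to one-tailed (greater than chance): the
published p-values for the preference tests match the upper-tail
computation at printed precision (e.g. t₈ = 1.98 → 0.0415 ≈ 0.0413),
while the one Control preference result matches a two-tailed computation;
since the convention is mixed at the source, both tails are always
reported. ANOVA uses the explicit sum-of-squares decomposition; Tukey HSD
uses the studentized range with the Tukey–Kramer correction for unequal
group sizes. Calibration suites verify the type-I error of both the Tukey
pairs and the direction effect at α = 0.05 on null simulations.

## Reduced-scale testing

Tests and the analysis drivers run the study at reduced durations and
subject counts (e.g. 20–120 s observation windows, 4–6 subjects) because
trial structure, bookkeeping and estimator behaviour are
duration-invariant and the full 5 × 10 × 20-minute protocol would waste
minutes of compute per run; all protocol-scale values remain the package
defaults. The acceptance suite's surrogate-coverage check uses 100
repetitions × 100 surrogates on length-500 series, sizes chosen for the
compute budget, not for the outcome.

## Known limitations

- The locomotion generator's event-mode dynamics are invented magnitudes;
  only its geometry, sampling and cruise statistics are protocol-anchored.
- Piecewise-linear waypoint interpolation underestimates the replica's
  path length and speed between waypoints.
- The tracker handles at most a few well-separated targets and does no
  appearance modelling; crossing targets closer than the per-frame
  displacement can swap identities (logged, not corrected).
- The plug-in transfer-entropy estimator is biased at segment lengths
  near the 175-sample minimum; the surrogate null quantifies but does not
  remove the bias, and no kernel/KSG continuous estimator is provided.
- The fixed-effects reading of the direction × segment test is an
  interpretation of an under-specified error structure, chosen to match
  the published df pattern.
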