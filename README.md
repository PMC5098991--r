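# roboshoal

Analysis pipeline for zebrafish binary-choice experiments with a
robotically actuated fish replica, rebuilt as a tested, reusable R package
exercised end to end on synthetic data.

## The problem

In the binary-choice assay a focal zebrafish swims in the central
compartment of a 74 × 30 × 30 cm tank (water depth 15 cm) flanked by two
10 cm lateral compartments behind transparent partitions; one side holds a
stimulus — here a 3D-printed zebrafish replica manoeuvred in three
dimensions by a robotic platform — and the other is empty. Two orthogonal
cameras (top and front, 30 frames/s) record each 20-minute trial (10 min
habituation + 10 min observation). The analysis questions are: does the
fish prefer the stimulus side, does the stimulus modulate its activity and
depth preference, and does information flow from the stimulus to the fish?

The package implements every stage for people running (or simulating) this
assay:

- **Synthetic data** — a mode-switching locomotion generator (cruise,
  freezing, thrashing, erratic movement, diving), replica waypoint programs
  (2.5 s sampling, 2 Hz / 10° peak-to-peak body-oscillation heading with
  mean 45°/135°), coupled fish–stimulus pairs with known directional
  coupling, and rendered two-view image sequences with ground truth.
- **3D tracking** — median background estimation, blob detection with
  intensity-weighted centroids, greedy nearest-neighbour track linking with
  gap interpolation, 18-frame moving-average smoothing, cross-correlation
  view synchronization, and orthogonal-view fusion with a QC x-discrepancy.
- **Behavioral metrics** — time budgets over three 18 cm length sections
  and three 5 cm depth levels, preference indices
  PI = T_N / (T_N + T_F) and T_B / (T_B + T_T), shoaling time within a
  12 cm radius, speed/acceleration by first-order differencing, and
  occupancy/speed histograms.
- **Transfer entropy** — the order-1 plug-in estimator
  T_{Y→X} = Σ p(x_{t+1}, x_t, y_t) log₂ [ p(x_{t+1}|x_t, y_t) /
  p(x_{t+1}|x_t) ] on width-coordinate series, with wavelet denoising,
  near-section segment gating (≥ 175 samples), 10-bin discretization,
  per-segment length normalization, and time-shift surrogate nulls.
- **Statistics** — IQR outlier screening, one-sample t-tests against
  chance (0.5), one-way ANOVA with Tukey HSD, and the direction × segment
  ANOVA of normalized transfer entropy.
- **Orchestration** — `run_trial()` / `run_study()` execute the five
  conditions (RM moving replica, RM2D planar replica at 7.5 cm depth, R
  static replica, M transparent moving model, Control bare rod with the RM
  program as virtual stimulus) with balanced stimulus sides and
  reproducible seeds.

## Worked example

The numbered drivers under `analysis/` run the whole sequence on a
reduced-scale study (2 min analysed observation, 6 subjects per condition;
package defaults keep the full protocol durations) and write their tables
under `results/`:

```sh
Rscript analysis/01_replica_program.R
Rscript analysis/02_track_synthetic_video.R
Rscript analysis/03_run_study.R
Rscript analysis/04_transfer_entropy_validation.R
Rscript analysis/05_stats_battery.R
```

Script 02 renders two-view synthetic video of a simulated fish and tracks
it back:

```
synchronization lag: 0 frames
per-axis RMSE vs truth: x 0.041, y 0.059, z 0.037 cm
QC x-discrepancy between views: 0.019 cm RMS
```

so the full background-subtraction → detection → linking → smoothing →
fusion chain recovers the ground-truth 3D trajectory to well under a
millimetre-scale error at 3 px/cm. Script 04 validates the directional
machinery on pairs with known one-way coupling `c` (stimulus → fish):

```
  c_strength te_stim_to_fish te_fish_to_stim
1        0.0          0.0504          0.0634
2        0.2          0.1809          0.0388
3        0.5          0.4294          0.0408
4        0.8          0.8171          0.0410
directional recovery at c = 0.8: 20 / 20 runs
```

TE in the driven direction grows with coupling strength while the reverse
direction stays at the estimator's bias floor; with no coupling the
estimate falls inside the 95% surrogate null band. Script 05 prints the
statistical battery (t-tests vs chance, between-condition ANOVA with Tukey
HSD, direction × segment ANOVA); because the simulated focal fish is
autonomous, its study-level transfer entropy is a null — the positive
control lives in script 04.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the replica heading signal with the package and recomputes its
protocol-level characteristics — the time-averaged heading when moving in
the positive-y direction, the peak-to-peak oscillation span, and the
dominant periodogram frequency — writing them as JSON.

## Layout

- `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (the brute-force transfer-entropy oracle lives in
  `tests/testthat/helper-oracles.R`).
- `analysis/` — the numbered narrative drivers above.
- `vignettes/robotic-replica-assay.Rmd` — models, assumptions, parameter
  choices and limitations.
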