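---
title: "Monitoring an isometric stance on a pressure mat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring an isometric stance on a pressure mat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancemat)
```

`stancemat` implements the computational pipeline behind a pressure-mat
balance trainer for the wide horse stance (Mabu): a static, wide-footed
isometric squat in which the practitioner should keep the feet wider than
shoulder width on the mat's centre-line, toes slightly out, and the body
weight evenly distributed — between the feet and between heel and forefoot
— for as long as possible. The package turns raw pressure matrices into
centre-of-pressure (COP) trajectories, validates and calibrates the entry
stance, classifies every training frame as good or poor posture, drives the
session timer and reward mechanics, and analyses multi-condition training
experiments. A parametric simulator stands in for the hardware, so the
whole pipeline is testable against known ground truth.

## The sensing model

The mat is a grid of piezoresistive cells read at fixed resolution. The
default `sensor_config()` is 22 rows x 42 columns = 924 cells at 12 bit
(raw values 0-4095) over a 1000 x 500 mm surface. Only the cell count,
bit depth and surface size are fixed by the hardware; the 22 x 42
factorisation is this package's choice (any `rows * cols` layout can be
configured). Coordinates: `x` along the 1000 mm axis, `y` along the 500 mm
axis pointing posterior-to-anterior, cell centres at `(index - 0.5) * pitch`.

Three preprocessing steps precede all analysis:

1. **Filtering** (`filter_frame()`): every cell below a threshold `beta` is
   zeroed. This removes the preload of the mat's foam layers and the noise
   floor. `beta` defaults to 2% of full scale (81.9 raw units) — a tuning
   choice, exposed in the configuration, not a hardware constant.
2. **Segmentation** (`split_left_right()`): in a wide stance the left foot
   is on the left half of the mat and the right foot on the right half, so
   segmentation is a plain column split. With an odd column count the extra
   column goes to the right half (a documented convention). Total pressure
   is conserved exactly.
3. **COP computation** (`compute_cop()`): the pressure-weighted centroid of
   the cell-centre coordinates, the standard baropodometric definition.
   The overall COP is exactly the load-weighted mean of the two half-frame
   COPs, which the tests exploit as an invariant.

## Foot geometry

Each half-frame is treated as one plantar pressure blob (`detect_foot()`).
Its centroid is the half-frame COP. The toe-out angle is the angle of the
pressure-weighted principal axis (second central moments) from the anterior
axis, reported outward-positive per side; the 180-degree axis ambiguity is
resolved anteriorly. The heel/forefoot split cuts the blob with the
perpendicular to the principal axis through the blob centroid.

Real (and simulated) filtered frames contain speckle: isolated cells whose
noise excursion clears `beta`. Shape estimation is therefore robustified in
three inexpensive, standard steps, none of which involve a tunable fit:

* **support**: only loaded cells with at least two loaded 8-neighbours
  enter shape estimation (isolated speckle has none);
* **components**: supported cells are grouped into connected components
  (connectivity bridges one-cell gaps, since a lightly loaded midfoot can
  dip under `beta` between the heel and forefoot lobes), and every
  component carrying at least 10% of the heaviest component's load is kept.
  The 10% floor keeps a lightly loaded forefoot and excludes speckle
  clusters, which are orders of magnitude lighter than a foot;
* **robust moments**: moment weights are the cell values minus the blob's
  minimum loaded value (background subtraction — rim cells hovering at the
  threshold get almost no leverage, and a constant offset cannot bias an
  axis), with two trimming passes that drop cells beyond Mahalanobis
  distance 3.

The centroid and the total load deliberately use the *whole* half-frame,
not the denoised blob, so `detect_foot()$centroid` remains exactly the
half-frame COP.

`stance_metrics()` reduces two feet to the quantities the validator needs:
stance width (distance between centroids), per-foot centre-line offset
(`|y - 250|` mm), and the load imbalance `|Pl - Pr| / (Pl + Pr)`.

## Entry validation and calibration

`validate_entry_stance()` checks five criteria; the stance is valid only if
all five pass. The toe-angle band 0-45 degrees is the one bound taken from
published stance practice; the remaining thresholds are tuning defaults
exposed in `stance_thresholds()`:

| criterion | default bound | note |
|---|---|---|
| left/right imbalance | <= 0.15 | fraction of total load |
| centre-line offset | <= 40 mm | per foot |
| stance width | >= 400 mm | or 1.2 x a measured shoulder width |
| toe-out angle | in [0, 45] deg | inclusive bounds, per foot |
| heel/fore imbalance | <= 0.30 | per foot |

`calibrate()` runs the validator on the calibration frame and freezes the
three reference COPs (overall, left, right), the foot geometry and the
region radius `alpha` into a profile; an invalid stance signals a
`stancemat_redo_calibration` condition carrying the failed criteria, the
package's form of "redo the calibration". An optional multi-frame
averaging window (default 1) damps sensor noise at capture time.

## The good/poor posture monitor

A training frame is good posture (`Ms`) iff every check passes; any raised
flag makes it poor (`Mp`). The primary check is the COP region test: each
of the three COPs must stay within `alpha` (default 40 mm, configurable; a
value of this order would be fitted per deployment in pilot trials) of its
calibrated reference. Two region shapes exist because the source material
for this design states per-axis bounds in its equations while describing a
"circular area" in prose: the default `box` mode applies the strict
per-axis bounds exactly as the equations print them (`d = max(|dx|, |dy|) /
alpha`, inside iff `d < 1`, so a displacement of exactly `alpha` is
already outside); `circle` mode uses the Euclidean distance. The circle is
inscribed in the box, so circle-inside implies box-inside — an invariant
the tests check on random triples.

Secondary flags: `foot_position` (a centroid drifted more than 50 mm from
calibration, or a foot left the mat), `foot_orientation` (a toe angle left
the 0-45 band or drifted more than 15 degrees from calibration) and
`lr_imbalance`. The drift defaults are tuning choices.

The normalised displacement `d` (the maximum over the three COPs) also
drives the four-state lean-severity feedback that the game renders as
platform colours: balanced/grey for `d <= 0.4`, slight/yellow up to 0.75,
severe/red below 1, broken/fall at `d >= 1`. Band edges are configurable.

`session_step()` implements the timer: each good frame adds one frame
period (default 20 fps); the first poor frame (debounce default 1 —
matching an immediate-stop reading; a longer debounce is configurable)
freezes the timer, records the break time, emits a notification event (the
headless counterpart of the in-game sound) and moves the session to the
terminal `BROKEN` phase. `run_session()` wraps the whole stream: an entry
phase gated by the validator, the training loop, and a per-frame JSONL
log; a stream that never produces a valid entry stance yields an aborted
record.

## Gamification

Levels ascend every 10 s of correctly held stance starting at Level 0
(`floor(duration / 10)`; exactly 10.0 s awards Level 1), with groups
beginner (0-6), intermediate (7-12), veteran (13-18) and expert (19+).
The leaderboard ranks by duration, breaking ties by earlier recording and
keeping each participant's best session — the tie and duplicate policies
are this package's choices.

## The synthetic-stance simulator

`synth_frame()` renders a stance as two anisotropic Gaussian pressure
lobes per foot — heel at -80 mm and forefoot at +80 mm along the foot
axis, sigmas (25, 22) and (30, 30) mm — rotated by the toe angle. The
two-lobe shape is the simplest model that reproduces the heel/sole
hotspots of real wide-stance heat maps, and the 160 mm lobe separation
against 25-30 mm axial sigmas keeps the centroid-boundary heel/fore
estimator accurate to within 0.05 over the realistic 0.35-0.70 split
range. Total raw pressure is proportional to body mass, scaled so an 80 kg
subject peaks near 60% of full scale (using the sensor's range without
saturating); truncated-Gaussian noise is added and values are quantised to
the bit depth. The returned ground-truth labels are the continuous-model
COPs, angles and splits.

A lean is imposed as a *weight redistribution*, the way a person leans
without moving the feet: the lateral component shifts load between the
feet and the anterior component shifts each foot's heel/forefoot split.
The two adjustments are solved jointly (a short fixed-point iteration) so
the overall COP moves by exactly the requested vector despite the x/y
coupling that toe-out introduces. Foot translations are a separate control
(`shift_left_mm` / `shift_right_mm`) because they model a different fault —
repositioned feet rather than a lean — and trigger a different monitor flag.

`synth_session()` scripts a full session: a bounded mean-reverting
(Ornstein-Uhlenbeck-like) sway of the COP (default amplitude 8 mm,
timescale 1 s — quiet-standing-like values well inside `alpha`) until the
scripted break time, then one of three break trajectories mirroring how
real stances end: `lean_out` (lateral weight shift past the region),
`foot_shift` (one foot moved 80 mm) and `rise` (standing up, unloading the
mat). Streams are deterministic per seed.

`synth_condition_cohort()` emulates the three-condition training
experiment — no feedback (NFB), stopwatch feedback (CFB), full game
feedback (GFB) — by drawing held durations log-normally with condition
medians 40 / 55 / 80 s and `sdlog = 0.35`. The effect ordering GFB > CFB >
NFB encodes the finding the experiment design anticipates; the magnitudes
are simulation choices fixed once from a design-time power calculation
(n = 14 per condition, the study scale, gives ~99% power for the GFB-NFB
rank-sum contrast at these settings). What passing tests on this cohort
show is that the *analysis pipeline* detects an effect of this size at
this sample size — not anything about real participants.

## Session analytics

`mann_whitney_u()` is a self-contained rank-sum test: midranks for ties,
`U_x = R_x - n_x(n_x+1)/2`, exact p by complete enumeration of all
`choose(n, n_x)` group assignments when `n <= 12` (enumeration stays
desk-fast there), otherwise a normal approximation with tie correction and
continuity correction. Two-sided p doubles the smaller tail, capped at 1.
The tests cross-check it against an independent pair-count enumeration
oracle and against `stats::wilcox.test()`.

`summarize_conditions()` produces box-plot summaries per condition —
median and quartiles by linear interpolation (the default, type-7,
quantile convention; the convention is stated because quartile definitions
differ), outliers by the 1.5 IQR rule — plus a rank-sum test of every
condition against the reference (NFB). All pairwise tests against the
reference are reported rather than a selected subset.

Heat maps are written as plain-text P2 PGM at the sensor's full gray range
(`render_heatmap()`), a lossless, diffable form of the familiar pressure
heat map; `read_pgm()` closes the round trip.

## Numerical choices and edge cases

* Zero total load is an error for COP computation and an abort/flag for
  the monitor, depending on context.
* Fewer than three supported cells, or a collinear cell set, is a
  degenerate blob: orientation is refused rather than guessed.
* `d = 1` exactly is outside the valid region (strict inequalities as
  printed in the defining bounds).
* Filtering with `beta = 0` is the identity; filtering is idempotent and
  monotone in `beta`.
* All randomness is seeded explicitly (`seed` fields; the caller's RNG
  state is restored), so frames, sessions and cohorts replay bit-for-bit.

## Problem sizes used in the checks

The automated checks run at deliberate desk scale: 50 seeded stances for
parameter recovery, 100 scripted sessions for break-time recovery, 10,000
random triples for the region-test equivalence, 1,000 small frames against
the brute-force COP oracle, 2,000 null replicates for the exact test's
type-I rate at n = (7, 7), and 100 cohort replicates at n = 14 per
condition for the scaled experiment replication.

## Known limitations

* One foot per mat half is assumed; gait, steps and multi-blob scenes are
  out of scope.
* The two-lobe Gaussian foot is a phenomenological stand-in: real plantar
  pressure shows toe-level structure, arch asymmetries and
  subject-specific shapes the simulator does not model, so estimator
  accuracy on simulated feet bounds, but does not guarantee, accuracy on
  real feet.
* Durations in the cohort generator are drawn directly from distributions
  rather than produced by simulating fatigue; the cohort exercises the
  statistics, not the biomechanics.
* The monitor's thresholds (`alpha`, drift limits, severity bands) default
  to plausible values and are meant to be fitted per deployment; none of
  them is a measured constant.
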