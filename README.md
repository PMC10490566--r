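# stancemat

Plantar pressure-mat analytics for isometric stance training.

`stancemat` is for researchers and developers working with grid pressure
mats (baropodometric sensors) who need to monitor a static, wide-footed
balance posture — the Shaolin horse stance (Mabu) in the motivating
application — in real time and to evaluate training interventions built on
top of that monitoring. It implements the full computational chain a mat-
based balance trainer needs, with a parametric simulator standing in for
hardware, so everything is reproducible from code.

## What it computes

Raw frames are matrices of 12-bit readings from a 924-cell mat
(22 × 42 cells over 1000 × 500 mm by default). The pipeline:

* **Filtering** — cells below a threshold β (default 2% of full scale) are
  zeroed, removing foam preload and the noise floor.
* **Segmentation** — the mat is split into left/right halves `Ml`, `Mr`,
  one foot per half.
* **Centre of pressure** — the pressure-weighted centroid
  `COP = Σ vᵢ xᵢ / Σ vᵢ` per foot (`COPl`, `COPr`) and overall (`COPo`).
* **Foot geometry** — toe-out angle from pressure-weighted second moments,
  heel/forefoot load split, stance width, centre-line offsets, left/right
  balance `|Pl − Pr|/(Pl + Pr)`.
* **Entry validation & calibration** — five pass/fail criteria for a
  correct wide stance (balance, centre-line, width, toe-out in [0°, 45°],
  heel/fore balance); a passing frame freezes the reference COPs into a
  calibration profile.
* **Monitoring** — a frame is good posture (`Ms`) while every COP stays
  within a radius α of its reference,

  `Ms: COPc − α < COPt < COPc + α` (per axis, strict; a circular-region
  mode is also available),

  plus drift checks on foot position and orientation. The normalised
  displacement `d` drives four feedback severities
  (balanced/slight/severe/broken), and a session state machine accumulates
  the held-stance timer until the first poor frame breaks the stance.
* **Gamification** — one level per 10 s held, groups
  beginner/intermediate/veteran/expert (levels 0–6 / 7–12 / 13–18 / 19+),
  and a duration-ranked leaderboard.
* **Simulation** — two-lobe Gaussian feet with ground-truth labels,
  scripted sessions (sway + lean/foot-shift/rise breaks), and log-normal
  three-condition training cohorts (NFB/CFB/GFB).
* **Analytics** — per-condition box-plot summaries with a from-scratch
  Mann-Whitney U test (exact by enumeration at small n), and plain-text
  PGM heat-map export.

See `vignette("stance-monitoring")` for the models, parameter meanings and
design decisions.

## Worked example

```r
library(stancemat)

# a calibration frame from the simulator (an ideal 450 mm stance, 18° toe-out)
frame  <- filter_frame(synth_frame(stance_spec(noise_sd = 10, seed = 42))$frame)
validate_entry_stance(frame)
#> # A tibble: 5 × 4
#>   criterion     measured  bound pass
#> 1 lr_balance     0.00187   0.15 TRUE
#> 2 centerline     1.21     40    TRUE
#> 3 stance_width 449.      400    TRUE
#> 4 toe_angle     18.2      45    TRUE
#> 5 heel_fore      0.0233    0.3  TRUE

profile <- calibrate(frame)
#> <calibration_profile> alpha = 40 mm
#>   COPo (499.6, 248.9)  COPl (275.3, 248.9)  COPr (724.7, 248.8)

# a scripted session: hold with natural sway, lean out at t = 24.6 s
session <- synth_session(stance_spec(noise_sd = 10),
                         session_script(break_mode = "lean_out",
                                        break_at_s = 24.6, hold_s = 30,
                                        seed = 7))
record  <- run_session(session$frames, profile)
glance(record)[, c("phase", "good_duration_s", "final_level", "terminal_flags")]
#> 1 BROKEN            24.6           2     cop_overall;lr_imbalance
```

The monitor recovers the scripted break exactly: 24.6 s held (level 2,
beginner group), ended by the overall COP leaving its region — the
signature of a lean, as scripted. A simulated three-condition cohort then
exercises the analytics:

```r
cohort <- synth_condition_cohort(seed = 42)   # n = 14 per condition
summarize_conditions(cohort)
#>   condition     n median_s  q1_s  q3_s outliers      U p_value
#> 1 NFB          14     45.8  38.6  64.3 <dbl [0]>    NA NA
#> 2 CFB          14     50.0  34.1  64.7 <dbl [0]>   105  0.765
#> 3 GFB          14     75.8  61.6  93.9 <dbl [0]>   154  0.0108
```

Game feedback (GFB) shows the longest held durations, and its rank-sum
test against no feedback (NFB) is significant at the 5% level in this
draw. `autoplot()` methods exist for frames, session records and condition
summaries.

A thin command-line front end over the same functions ships in
`inst/cli/stancemat.R` (subcommands: simulate, calibrate, validate,
monitor, leaderboard, report, heatmap).

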