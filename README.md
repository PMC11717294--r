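# chopgrip

Objective, video-based assessment of how children hold chopsticks.

Occupational therapists and researchers classify children's chopstick
grips into **four-finger prehension** (the traditional grip: the upper,
"movable" chopstick driven by fingers I–III while the lower, "fixed"
chopstick rests against finger IV), **three-finger prehension**, **palm
prehension**, and palm-like **others**. Rating videos by eye is slow and
subjective. `chopgrip` implements an objective pipeline that decides,
from single-camera video, whether a grip is *traditional* (four-finger)
or *nontraditional*:

1. **Chopstick detection** — the chopsticks carry blue (upper) and green
   (lower) identification tape; each frame is segmented in HSV space,
   the largest blob per color is reduced to a line segment by principal
   axis, and detection failures are bridged by a previous-frame
   carry-forward rule (bounded by `max_gap`).
2. **Hand-geometry features** — from the standard 21-point hand landmark
   layout (any pose-estimation backend, or the built-in simulator), four
   per-frame distances are computed: *a* fingertip II → upper chopstick,
   *b* first joint of finger III → upper chopstick, *c* fingertip III →
   lower chopstick (perpendicular point-to-line distances), and *d*
   fingertip III → fingertip IV (Euclidean).
3. **Time-series summarization** — each channel (the 4 distances plus
   the 10 fingertip coordinate trajectories) is collapsed to its
   **CO_f1ecac** statistic — the first lag at which the autocorrelation
   function crosses 1/e, a timescale of signal memory — plus mean and SD.
4. **Classification** — a Gini decision tree with importance-based
   feature weighting (fit, drop features below the importance quantile,
   refit); traditional-class training sequences are first doubled by
   scale/translation augmentation.

Because real recordings are rarely shareable, the package ships a
**synthetic hand-kinematics simulator**: articulated 21-landmark hands
(sinusoidal flexion about the knuckles, 2 open/close cycles per second
for 10 s at 30 fps), chopstick geometry per grip archetype, landmark
noise and detection dropout, and rendered tape-colored frames — so every
stage is testable end to end with known ground truth.

The accompanying **survey statistics** reproduce the questionnaire side
of such studies: DCDQ scoring (15 items, subscales 6/4/5), grip tallies,
Fleiss' kappa inter-rater agreement, Lilliefors (KS) normality
screening, multinomial logistic regression (Newton ML; odds ratios with
Wald CIs; optional sandwich covariance; listwise deletion) and
Nagelkerke pseudo-R², plus a synthetic survey generator with known
effect sizes for parameter-recovery validation.

## Worked example

```r
library(chopgrip)

# a synthetic study: 60 traditional + 103 nontraditional 10-second trials
ds <- make_grip_dataset(seed = 1)
ds
#> Grip dataset: 163 sequences (60 traditional, 103 nontraditional)
#>  four_finger        other         palm three_finger
#>           60           33           20           50

# augment -> features -> CO_f1ecac summaries -> stratified 5-fold CV
res <- assess_grip_dataset(ds, seed = 1)
round(res$metrics, 3)
#>  accuracy precision    recall        f1
#>     0.960     0.969     0.958     0.963
```

A single trial and its summary:

```r
s <- generate_grip_sequence("four_finger", trial_protocol(), seed = 42)
s
#> Grip sequence: four_finger (traditional), 300 frames at 30 fps, seed 42
#>   chopstick source: 297 detected, 3 missing
sm <- summarize_sequence(compute_features(s))
round(unclass(sm)[c("cof1ecac_a", "cof1ecac_d", "sd_d", "mean_a")], 2)
#> cof1ecac_a cof1ecac_d       sd_d     mean_a
#>       2.49       2.73       7.73      25.06
```

The `cof1ecac_*` values sit near 2.85 frames — the first 1/e crossing of
a 2 Hz oscillation sampled at 30 fps — confirming the trial's open/close
rhythm; `sd_d` captures how much finger IV moves independently of
finger III, the kinematic signature separating four-finger from
three-finger grips.

The survey side, on a synthetic cohort of 165 first-graders:

```r
survey <- make_survey_table(165, seed = 1)
fit <- fit_multinomial_logit(survey)   # reference: four_finger
fit
#> Multinomial logit (reference: four_finger), n = 165, logLik = -166.733
#>      contrast    predictor estimate    se      z     p    or or_lo or_hi
#>  three_finger cohabitation   -1.703 0.473 -3.601 0.000 0.182 0.072 0.460
#>    palm_other cohabitation   -1.636 0.451 -3.630 0.000 0.195 0.081 0.471
#>    ...
nagelkerke_r2(fit)
#> [1] 0.177
fleiss_kappa(survey[, c("rater1", "rater2")])
#> [1] 0.966
```

Grandparent–grandchild cohabitation emerges as a strong protective
factor for the traditional grip (OR well below 1 on both contrasts), as
encoded in the generator's effect sizes.

## Command line

A thin wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "chopgrip", package = "chopgrip"))') --help
chopgrip simulate --archetype four_finger --n 60 --seed 1234 --out dir/
chopgrip detect   --frames dir/ --out poses.csv
chopgrip features --landmarks lm.csv --out feats.csv
chopgrip train    --data dir/ --labels dir/labels.csv --out model.json
chopgrip classify --model model.json --landmarks lm.csv
chopgrip survey   --data survey.csv --out report/
```

Video input is a PNG frame stack (or in-memory arrays); landmark series
are CSV/JSON in the documented schema; models serialize to JSON.

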