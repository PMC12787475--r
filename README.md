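# rebamotion

Continuous, frame-wise **REBA** (Rapid Entire Body Assessment) ergonomic
risk scoring of full-body inertial motion-capture recordings, built for the
analysis of professional classical ballet training — and for anyone who
wants to turn suit-exported joint angles into duration-normalised
musculoskeletal risk profiles.

REBA composes per-frame body subscores through the published worksheet
tables:

```
Score A = TableA(neck, trunk, legs) + load
Score B = max over sides of TableB(upper arm, forearm, wrist) + coupling (= 0, nothing is held)
final   = TableC(Score A, Score B) + activity        (1 ... 14)
```

with the load score driven by vertical pelvic acceleration (no external
weight is carried when dancing) and the activity score by windowed
static-hold and spectral criteria. Vertical load in body-weight units is
estimated from the pelvis trajectory alone,

```
load = max(0, 1 + z"/g)     (z" = central second difference of pelvis height)
```

so quiet standing carries 1 BW and ballistic flight exactly 0 BW. Final
scores are banded 1 | 2–3 | 4–7 | 8–10 | ≥ 11 (negligible / low / medium /
high / very high), histograms are normalised to sequence duration, and
group contrasts use a nonparametric battery: Wilcoxon–Mann–Whitney,
Kruskal–Wallis with a Dunn-type pairwise follow-up, Bonferroni–Holm
correction, and Cliff's delta effect sizes.

The package also ships a **synthetic motion generator** that scripts a
condensed 80-minute professional class (barre / centre / jumps, 1358 s male
and 1410 s female of pure load time) with known frame-wise ground truth, so
the whole pipeline is testable without recorded human data.

## Worked example

```r
library(rebamotion)

plan <- default_training_plan()
total_duration(plan, "male")    # 1358 (seconds of pure load, male programme)
total_duration(plan, "female")  # 1410

## a small synthetic two-gender study (compressed durations for speed),
## with a scripted +3 deg trunk-flexion offset for the female group
study <- generate_study(plan, n_female = 6, n_male = 6, seed = 11,
                        sample_rate_hz = 60, time_scale = 0.1,
                        effect = list(joint = "jL5S1", dof = "flexion",
                                      delta_deg = 3))
res <- run_session(study$recordings, plan)
res
#> <session_result> 210 recordings, 12 subject(s), 99648 frames
#>   session mean REBA 4.01, mean load 1.00 BW
#>   risk bands (session):
#> negligible        low     medium       high  very_high
#>      0.002      0.306      0.691      0.000      0.000

res$comparisons$gender_overall
#> MWU: z = -2.642 (U = 1), p = 0.004329 *; Cliff's delta = -0.944 (large)

res$comparisons$phase_pairwise_reba
#>               pair rank_diff  lower upper      z  p_value   p_holm significant
#> 1 phase1 vs phase2    -20.08 -30.38 -9.79 -4.670 0.000003 9.01e-06        TRUE
#> 2 phase1 vs phase3     -4.17 -14.46  6.13 -0.969 0.332555 3.33e-01       FALSE
#> 3 phase2 vs phase3     15.92   5.62 26.21  3.702 0.000214 4.29e-04        TRUE
```

Reading the output: 69% of this synthetic session sits in the medium risk
band (score 4–7); the scripted trunk offset makes the female group's
per-subject mean REBA stochastically higher than the male group's
(negative z by the pipeline's male-vs-female convention, large negative
Cliff's delta), and the centre phase scores significantly higher than
barre and jumps. `render_report(res, "out/")` writes the histograms, band
summaries and the comparison battery as CSV and Markdown.

Lower-level entry points: `read_recording()` / `write_recording()`,
`compute_reba_series()`, `pelvis_load()`, `load_histogram()`,
`reba_histogram()`, `risk_bands()`, `mwu_test()`, `cliffs_delta()`,
`bonferroni_holm()`, `generate_sequence()`.

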