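# gazesal

Individual differences in semantic gaze salience from free-viewing
eye-tracking data.

When observers freely view complex scenes, they differ reliably in how much
of their gaze goes to *faces*, *text*, *touched* objects, objects with a
characteristic *taste*, and objects with implied *motion*. `gazesal` is an R
package for measuring these individual differences and for the psychometric
questions they raise: how reliable are the estimates, how few images and how
little viewing time suffice, and which stimulus subsets preserve validity. It
is aimed at vision scientists and clinical researchers who run (or plan)
free-viewing studies with object-annotated stimuli such as OSIE-style
catalogs.

## What it computes

For each observer $i$ and semantic dimension $d$, over an image set $S$:

* **cumulative dwell proportion**
  $p_{id} = \sum_{f \in F_i(S), d \in \mathrm{labels}(f)} t_f \Big/ \sum_{f \in F_i(S)} t_f$,
  where $F_i(S)$ are the retained, label-assigned fixations and $t_f$ their
  (possibly truncation-clipped) durations;
* **first-fixation proportion** — the share of trials whose first valid
  fixation carries $d$;
* **visual exploration** — the number of distinct objects fixated.

Fixations are assigned to every object whose binary pixel mask contains them
or lies within 0.5 degrees of visual angle (exact point-to-pixel Euclidean
distance; the angular radius is converted with the mean pixels-per-degree).
Central onset fixations (onset < 100 ms), fixations shorter than 100 ms and
unassignable fixations are excluded with per-reason bookkeeping.

On top of the estimates:

* **split-half consistency** over random image splits (median Pearson $r$
  across observers, Bonferroni-adjusted $p$, full split distribution);
* observer **ranges and max/min ratios** per dimension;
* **cross-set / cross-session validity** with a configurable $r \ge 0.7$
  threshold and **explainable variance** relative to a noise ceiling
  ($r^2_\mathrm{subset} / r^2_\mathrm{ceiling}$);
* **trial truncation** analyses (consistency of truncated with full-duration
  estimates; split-half reliability per cutoff);
* **greedy forward selection** of image subsets maximising the mean
  Fisher-z validity of prefix estimates against the full set, with
  out-of-session validity curves and nested subset export;
* a **generative gaze simulator** with stable per-observer biases and
  Spearman-Brown-based calibration of split-half reliability
  (`calibrate_reliability()`) and cross-session validity
  (`solve_session_noise()`).

## Worked example

Simulate a 40-observer, 120-image free-viewing session, score it, and ask how
reliable the individual differences are:

```r
library(gazesal)

cfg       <- sim_config(n_observers = 40, n_images = 120, seed = 7)
catalog   <- generate_catalog(cfg, seed = derive_seed(7, "catalog"))
observers <- generate_observers(cfg, seed = derive_seed(7, "observers"))
fixations <- simulate_session(observers, catalog, cfg,
                              seed = derive_seed(7, "day1"))

scores <- score_gaze(fixations, catalog)
scores
#> <gaze_scores> 40 observers x 120 images; 34799 fixations in
#>   retained (label-assigned): 18845 | excluded: onset 0, duration 3055, unassignable 12899
#>   assignment: union mode, radius 2.9 px

split_half(scores, n_splits = 500, seed = 7)
#> <consistency_result> dwell, 500 split(s)
#>  dimension median_r p_adjusted n_splits n_observers
#>      Faces    0.923    1.2e-16      500          40
#>       Text    0.775    2.2e-08      500          40
#>    Touched    0.769    3.5e-08      500          40
#>      Taste    0.786    9.1e-09      500          40
#>     Motion    0.880    3.6e-13      500          40

m  <- salience_matrix(scores)
rr <- range_and_ratio(m[, "Faces"])
sprintf("Faces dwell range %.0f-%.0f%%, max/min ratio %.2f",
        rr$min_pct, rr$max_pct, rr$maxmin_ratio)
#> [1] "Faces dwell range 11-64%, max/min ratio 5.79"
```

Reading: over 500 random halves of the image set, per-observer dwell
proportions correlate at a median `r = 0.92` for `Faces` between halves —
face salience is a highly stable individual trait in this (simulated) study —
while the least reliable dimension (`Touched`) still reaches `r = 0.77`. The
most face-prone observer spends 64% of assigned dwell time on faces, the
least face-prone 11%.

Real data enter through `read_fixation_table()` (delimited text with a
configurable column mapping) and `read_scene_catalog()` (a directory with
`geometry.yaml`, `labels.csv` and one grayscale PNG mask per object, named
`<image_id>__<object_id>.png`; users of `.mat` mask deposits should export to
that layout). `run_replication()`, `run_shortset()` and `run_truncation()`
bundle the full analyses into tidy CSV + Markdown reports;
`inst/cli/gazesal.R` exposes them as shell subcommands.

See the methods vignette (`vignettes/semantic-salience-methods.Rmd`) for the
model, the assignment numerics, the simulator and its calibration, and the
design decisions.

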