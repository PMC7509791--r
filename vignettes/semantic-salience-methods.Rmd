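---
title: "Measuring individual differences in semantic gaze salience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual differences in semantic gaze salience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesal)
```

## The problem

When people freely view complex everyday scenes, they differ reliably in
*what* they look at: some observers spend far more dwell time on faces, text,
touched or tasty objects, or objects with implied motion than others, and
these tendencies are stable across images and sessions. Such semantic
salience biases are candidate traits for basic vision science and for
clinical research (for example on social attention), which makes two
psychometric questions central:

1. **Reliability** — how consistently can an observer's bias be estimated
   from a finite set of images and a finite trial duration?
2. **Efficiency** — how small can the stimulus set and how short can the
   trials be before those estimates degrade?

`gazesal` implements the full measurement pipeline for these questions:
object-based fixation scoring against labelled pixel masks, per-observer
salience estimates, split-half and cross-session reliability, trial
truncation analyses, and greedy forward selection of stimulus subsets. A
generative simulator with controllable reliability makes every stage testable
end to end without any external data.

## Scoring fixations against scene objects

The input is a fixation table (observer, image, position in pixels, onset and
duration in ms, onsets relative to image onset) and a *scene catalog*: one
binary pixel mask per annotated object plus a label table assigning each
object a subset of twelve semantic attributes.

**Coordinate convention.** Pixels are 0-based with the origin at the top
left; the centre of pixel $(x, y)$ sits at continuous coordinates $(x, y)$. A
fixation is *inside* a mask when the pixel under `round(x), round(y)` is a
true mask pixel.

**Label preparation.** Neutral and emotional face labels are merged into a
single `Faces` dimension (their fixation tendencies covary strongly), and
overlap-reduction rules are applied: `Text` objects lose `Smell` and
`Watchable`; `Touched` objects lose `Operable` and `Gazed`. The rules are
independent, idempotent, and never touch masks; they are applied in a fixed
order purely for deterministic audit logs.

**Exclusion rules.** Central onset fixations (onset < 100 ms), fixations
shorter than 100 ms, and fixations that cannot be assigned a label are
excluded, in that priority order, with per-reason tallies kept. The onset
rule is implemented as an onset-*time* rule, not a screen-position rule.

**Assignment.** A fixation is assigned to every object whose mask contains
it; otherwise to every object whose mask lies within 0.5 degrees of visual
angle (a `nearest`-object mode is available for the near-miss case — the
union is the default because it avoids arbitrary tie-breaking and matches
label-level scoring). The angular radius is converted to pixels with the
*mean* of the horizontal and vertical pixels-per-degree: wide-screen set-ups
are anisotropic (a 1920 x 1080 px display spanning 29.0 x 22.2 degrees has
66.2 vs 48.6 px/deg), and the mean treats a radial threshold symmetrically.

**Distance computation.** Distances to a mask are computed exactly, as the
minimum Euclidean distance from the fixation to any true pixel centre, using
only the mask's *boundary* pixels (true pixels with a false 4-neighbour or on
the image edge). For a point whose containing pixel is false, the nearest
true pixel is always such a boundary pixel — if an interior pixel were
nearest, its neighbour towards the point would be at least as close — so the
boundary shortcut is not an approximation. The test suite verifies exact
agreement with a brute-force scan over every true pixel on hundreds of
randomised mask/fixation configurations. Masks must match the display
resolution exactly; no rescaling is ever performed, to avoid silent
coordinate drift.

## Salience measures

For each observer, over any image subset and optional truncation cutoff:

* **Cumulative dwell proportions** — the share of label-assigned dwell time
  on objects carrying each dimension. Labels overlap, so the five tested
  dwell dimensions (`Faces`, `Text`, `Touched`, `Taste`, `Motion`) need not
  sum to 1; each cell lies in $[0, 1]$.
* **First-fixation proportions** — the share of trials whose first retained,
  label-assigned fixation carries each dimension (`Faces`, `Text`, `Touched`
  are the tested set). If the literal first fixation of a trial was excluded,
  the next surviving fixation is used by default; `strict_first = TRUE`
  drops such trials instead (both conventions are defensible, so both are
  provided).
* **Visual exploration** — the number of distinct objects fixated.

Observers without valid data on a subset are *missing*, never zero, and
missingness propagates into correlations by pairwise deletion. The dwell
denominator is label-assigned fixation time only, mirroring the exclusion of
unassignable fixations from the dataset before proportions are formed.

**Truncation** clips trials at a cutoff: fixations starting later are
dropped; a fixation spanning the cutoff keeps its partial dwell
(`cutoff - onset`). Clipping preserves total-viewing-time accounting;
first-fixation analyses are only ever shortened, never re-ordered.

## Reliability and validity analyses

**Split-half consistency.** Images are partitioned uniformly at random into
two halves (1000 splits by default; a deterministic odd/even `parity` mode is
also provided), the salience matrix is computed per half, and the halves are
Pearson-correlated per dimension across observers. The distribution over
splits is kept; the summary is the median r. A p value for a median of
correlated split r's has no exact form; the package uses the t transform of
the median r with $n - 2$ degrees of freedom — a conservative convention —
Bonferroni-multiplied by the number of tested dimensions (5 for dwell, 3 for
first fixations) and capped at 1.

**Ranges and max/min ratios.** The observer minimum and maximum (in percent)
and their ratio, reported in the max/min orientation so ratios are at least
1 (summary tables in this literature print that orientation even where the
surrounding text says min/max).

**Cross-set validity.** Per-dimension correlation between two salience
matrices joined by observer id (for example, subset estimates from a second
session against full-set estimates from the first), with a configurable
validity threshold of $r \ge 0.7$.

**Explainable variance.** Because a finite retest reliability caps the
attainable validity, subset validity is also reported relative to a noise
ceiling: $r_\mathrm{subset}^2 / r_\mathrm{ceiling}^2$ by default (the ratio
is about shared *variance*); a plain $r$-ratio mode is provided since both
conventions appear in practice. Ceiling values are configuration, not
constants: the package defaults interpolate a plausible per-dimension profile
(0.68–0.84) and should be replaced by study-specific retest estimates where
available.

## Greedy stimulus-subset selection

`greedy_select()` orders images so that each prefix maximises the congruence
between prefix-based and full-set-based observer estimates on the training
data. The objective is the unweighted mean, over the five dwell dimensions,
of Fisher-z-transformed Pearson correlations. Two numerical choices matter:

* $|r|$ is capped at 0.99 before the z transform. As prefixes approach the
  full set the correlation approaches 1 and z diverges; the cap keeps the
  objective finite and comparisons meaningful. The cap is part of the
  objective definition and is applied identically in the exhaustive-search
  oracle used by the tests.
* Below three images a correlation objective is unstable. For sets of at
  most 50 images the first three images are seeded by exhaustive search over
  all triples; for larger sets the seed is the best single image followed by
  greedy growth (the method used is recorded in the result).
* A dimension whose prefix correlation is undefined (no variance, or no
  image in the prefix carries the label) contributes *zero* to the mean
  rather than being dropped: dropping it would reward prefixes that miss a
  dimension entirely, an objective under which forward selection measurably
  diverges from the exhaustive optimum.

Ties break towards the lexicographically lowest image id. The search is pure
forward selection (one image per step, no backtracking or swaps). Prefixes
are nested by construction, so exported subsets of sizes 40/100/200 satisfy
$S_{40} \subset S_{100} \subset S_{200}$.

Selection is evaluated *out of session*: the ordering is chosen on one
dataset and validity curves are computed on an independent session against
the first session's full-set reference. In-sample curves are optimistic —
the simulator makes this overfitting visible, and the test suite checks that
greedy orderings still beat random orderings out of session.

## The synthetic-data generator

The generator emulates the structure of an OSIE-style free-viewing study —
about 100 observers, up to 700 images, 3-second trials — with a known
individual-difference structure:

* **Catalog.** Per image, 5–10 rectangular or elliptic masks (overlaps
  allowed) on a 192 x 108 px display spanning 29.0 x 22.2 degrees (the
  canonical wide-screen geometry scaled down tenfold so hundreds of pixel
  masks stay cheap; all angular thresholds scale with it). Raw labels are
  sampled per dimension as independent Bernoulli draws, except that emotional
  faces require a face; prevalences are ordered as in real scene corpora
  (faces most frequent, touched/tasty objects least). Labels are sampled
  *before* preparation, so the merge and overlap rules are exercised on every
  fixture.
* **Gaze model.** Observer $i$ carries a stable log-salience bias per tested
  dimension, drawn from $N(0, \sigma_d)$. On each trial, every object gets
  the weight $\exp(b_o + \sum_d (\mathrm{bias}_{id} + \mathrm{session}_{id} +
  \mathrm{trial}_{ijd}) \cdot [d \in \mathrm{labels}_o])$, a constant-weight
  background target competes with the objects, and each fixation picks a
  target from the softmax. The first fixation of a trial has its bias term
  multiplied by a bottom-up weight (default 0.8; set to 1 for time-stationary
  fixtures). Positions are object centroids plus Gaussian jitter; dwell is
  Gamma distributed; onsets are sequential with a 30 ms saccade gap, start at
  or after 100 ms (so generated data survive the default filters), and the
  trial is clipped at 3 s. Fixation counts are Poisson, scaled by a
  log-normal per-observer exploration rate. This is the simplest process that
  produces stable rank-order individual differences with tunable reliability;
  the analyses assume only the between/within variance structure, not a
  specific gaze model.
* **Default bias spreads** (`Faces` 0.80, `Text` 0.70, `Touched` 0.65,
  `Taste` 0.65, `Motion` 0.60 on the log-salience scale) were chosen once so
  that the generator's zero-noise reliability ceiling lies above the highest
  split-half consistencies reported for such studies (about 0.96) on *every*
  tested dimension at 700 images — the calibration range must cover the
  phenomena being modelled — while prevalence differences still make
  face/text estimates the most reliable at matched noise, as observed
  empirically.

**What the simulator does not emulate.** Centre bias, saccade dynamics and
amplitude statistics, pixel-level saliency, object shapes beyond
rectangles/ellipses, image-level semantic context, and any task effects.
Passing tests on synthetic data therefore demonstrate that the *analysis
machinery* is correct and well-calibrated under a known generative process —
not that any particular empirical effect size holds in real data, which
requires real fixation tables and mask catalogs supplied in the documented
formats.

## Reliability calibration

Because images are exchangeable draws from the generator, the split-half
reliability of a $k$-image aggregate follows the Spearman–Brown relation
$r(k) = k\lambda / (1 + (k - 1)\lambda)$ in the per-image reliability
$\lambda$. `calibrate_reliability()` solves the per-dimension trial-noise SD
for a target split-half r:

1. the target is mapped through the Spearman–Brown inversion to the
   calibration grid's set size (by default the grid *is* the study's image
   set, so no extrapolation is needed — the relation is exact only for
   homogeneous items, and per-image information is heterogeneous here);
2. grid reliabilities are *measured* by simulating observers and scoring them
   with the actual pipeline, under common random numbers so the measured
   reliability is a smooth monotone function of the noise SD;
3. the noise SD is bracketed on a ladder and refined by secant steps until
   the grid reliability is within tolerance (0.015 by default).

Targets above the zero-noise ceiling raise an error; targets within
measurement margin of the ceiling return zero noise with a warning.
`solve_session_noise()` applies the same machinery to between-session noise,
root-finding on the measured cross-session validity at the study's own set
size (which automatically accounts for attenuation by measurement
unreliability).

## Problem sizes and numerical conventions

The test suite exercises the pipeline at the scale the generator is designed
for — reliability recovery at 100 observers x 700 images with 200 splits,
cross-session attenuation at 100 x 300, truncation and selection at 60–80
observers and 100–400 images — and smaller hand-built fixtures for exact
arithmetic checks. Reported correlations at n = 100 observers carry sampling
SDs near $(1 - r^2)/\sqrt{n} \approx 0.05$; recovery checks therefore
evaluate the mean over the five calibrated dimensions, which estimates the
common target with roughly $\sqrt{5}$ less noise, alongside looser
per-dimension sanity bounds.

Other conventions: all randomness flows from one root seed split per stage
via `derive_seed()` (reruns with the same configuration are byte-identical);
constant vectors yield missing correlations rather than errors; Bonferroni
adjustment is `min(1, k p)`; duplicated subset sizes collapse with a warning;
degenerate geometry (pixels-per-degree differing by more than a factor two)
is rejected at construction.

## Limitations

* The per-image reliability framework treats images as exchangeable; strongly
  clustered stimulus sets (for example, blocks of face-free images) would
  need stratified splits, which the package does not implement.
* The p value attached to a median split-half r is conservative and should
  not be interpreted as an exact test.
* Greedy forward selection has no optimality guarantee; the tests bound its
  gap to the exhaustive optimum only on small sets (within 10% there), and
  integer-programming alternatives are out of scope.
* Mask input is pixel-perfect by design: catalogs at a different resolution
  than the display must be converted upstream.
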