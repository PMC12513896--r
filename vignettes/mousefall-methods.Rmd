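---
title: "Simulating and analysing a gamified mouse-tracking task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a gamified mouse-tracking task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The paradigm

mousefall models a web-based mouse-tracking task for spoken-word
recognition, built like an early arcade game. Two objects fall from the top
of the screen while a spoken sentence plays; one object is named in the
sentence (the target). The participant steers a spaceship along the bottom
of the screen with the mouse and either catches the falling target or ends
the trial early with a "tractor beam" click. Because the objects wiggle
unpredictably left and right inside fixed horizontal corridors, committing
to one object early — as soon as the speech disambiguates it — is the
rewarding strategy, and the cursor trace becomes a continuous record of
lexical commitment, analogous to fixations in the visual-world paradigm.

The primary dependent measure is the **decision time**: the start of the
last continuous cursor movement that ends inside the target's corridor.
Because the game can be played in a browser at whatever frame rate the
participant's machine provides, the analysis must first normalize
variable-frame-rate cursor logs onto a fixed grid.

The package provides both halves of a measurement-validation loop:

* a **generative simulator** of the trial dynamics and of synthetic
  participants with *known* latent commitment times, and
* the **full analysis pipeline** — regridding, decision-time extraction,
  screening, mixed-effects models, within-participant error bars and a
  bootstrap time-course analysis —

so that the paradigm's measurement properties (parameter recovery, exclusion
behaviour, effect detection, false-positive rates) can be studied without
collecting data.

## Trial dynamics

Coordinates are normalized: x runs over \([-0.5, +0.5]\) in screen widths
with 0 at the centre, y over \([0, 1]\) bottom to top. The task itself never
states physical units, so normalized units keep every tolerance
resolution-independent.

Per display frame, each object's horizontal direction reverses if a uniform
draw falls below `flip_prob` = 1/40, or — taking precedence — if the next
step would leave the object's corridor. Exactly one draw is consumed per
object per frame, so trial logs are bit-identical functions of
`(config, seed)`. The vertical fall rate is set per trial so that the
objects reach their lowest point no earlier than 2 s after the target-word
onset:

\[ T_{\mathrm{fall}} = \max(T_{\mathrm{base}},\; t_{\mathrm{onset}} + 2\,\mathrm{s}), \]

with `base_fall_s` = 3 s. Target onsets in the simulated stimulus inventory
span 0.73–3.26 s, so late-onset trials fall for up to 5.26 s. Trials end
200 ms after a click (or 200 ms after the audio ends, if the click came
during playback); without a click they end when the objects reach the
bottom. All animations freeze at the click. A catch counts as successful
when the final spaceship–target distance is strictly below 5% of the screen
width.

Free geometry parameters the task description does not constrain — the
corridor extents (default \([0.08, 0.40]\) on each side, boundaries closed)
and the ship height — are configurable in `screen_geometry()`. The
horizontal object speed (0.25 screen widths/s) was set so an object
traverses its corridor in roughly 1.3 s, long enough to reward early
tracking.

## Synthetic participants

An `agent_profile()` is a minimal behavioural model, not a cognitive one:

* a latent **commitment time**, `base_commit_s` after target onset, plus
  additive condition shifts (`effect_map`) and zero-mean Gaussian noise
  (`commit_sd_s`);
* **tracking** as exponential relaxation toward the chosen object's current
  position with time constant `track_lag_s` (simpler than minimum-jerk
  trajectories and with one interpretable parameter; the task record cannot
  constrain a richer movement model);
* white positional **jitter** (`jitter_sd`), applied to positions rather
  than velocities so regridding behaves identically in distribution across
  frame rates;
* a **strategy flag**: clickers fire the tractor beam `click_delay_s` after
  committing once aligned with the object; non-clickers let objects fall
  and therefore contribute no reaction times (structural missingness, as in
  real cohorts);
* occasional **initial guesses** (`guess_prob`): shortly after the trial
  starts (0.2–0.6 s in) the agent picks a random side. Correct guesses are
  typically on the target for the whole analysis window and so are lost to
  decision-time extraction ("always on target"); wrong guesses are tracked
  to the wrong object and surface as errors. Guessers wait for the target
  word before clicking.

Default population parameters: 40 participants, 80% clickers,
`base_commit_s` drawn from N(0.5 s, 0.12 s) across participants,
`commit_sd_s` = 0.15 s within participants, `track_lag_s` = 0.15 s,
`jitter_sd` = 0.003, `click_delay_s` = 0.3 s, `guess_prob` = 0.04, and host
frame rates drawn from {30, 60, 75, 144} fps with ±1 ms timestamp jitter.
These values were chosen once to produce decision-time distributions,
accuracies (~90–95%), always-on-target losses (~2–4%) and clicker fractions
of the magnitude reported for real cohorts on this task; condition effect
defaults (60 ms reduction cost, 135 ms semantic-competitor cost) are of the
magnitude reported in the motivating studies. They are simulation inputs,
not estimates.

What the generator deliberately does **not** emulate: vertical cursor
movement (the analysis uses x only), within-trial changes of mind,
speed–accuracy trade-offs, fatigue or practice effects, device-specific
motor noise (mouse vs touchpad appears only as a grouping column), and any
dependence of commitment on the acoustics beyond the target onset. Passing
recovery tests therefore show that the *pipeline* faithfully measures
commitment times of this simple agent — they do not validate the paradigm
against richer human behaviour.

## Preprocessing and decision times

Cursor logs are normalized onto a fixed grid from 0.5 s before to 2 s after
target onset at 60 Hz — 151 points, one every 16.67 ms. Each grid point
takes the temporally **nearest** observed position (no interpolation). Two
cases the rule leaves open are fixed as: a grid point exactly halfway
between two samples takes the *earlier* one, and grid points before the
first observation take the first (participants start on the spaceship at
the centre, so this extension is natural). Points after the last
observation are padded with the last position, and `pad_from` records where
padding began. Grid timestamps are computed as `t_start + i/rate` so the
point count is exact on every platform.

Trajectories are then oriented: x is multiplied by −1 when the target is on
the left, so positive always means "toward the target". Each sample is
categorized as `t` (inside the target corridor, boundaries inclusive), `l`
(step toward the target larger than `eps`), `r` (step away), or `s`
(stable). Note that `l` here means *toward the target* on the oriented
axis. The stability threshold `eps` = 10⁻³ screen widths is smaller than
any plausible intentional per-frame movement at 60 Hz.

The decision time is extracted from the 151-character state string: the
latest `lt` pair marks the last entry into the corridor; from its `l` the
algorithm backtracks through the maximal *contiguous* run of `l` states
(an interleaved `s` breaks the run — the strict reading of "where the
movement started") and returns the grid time of the run's first sample. If
the cursor instead sat stable just outside the corridor and entered it
within one frame, the latest `st` pair is used when it lies later than the
last `lt`; its `t` sample — the moment of corridor entry — is the decision
time. All-`t` strings (correct early guesses) are `NA` with reason
`always_on_target`; strings without any corridor entry, including the
corner case of a trace that starts inside the corridor and leaves without
returning, are `NA` with reason `never_reached_target`. Negative decision
times (commitment before onset) are legal and flagged by their sign, since
the grid starts at −0.5 s.

## Screening

Applied in order: (1) participants with strictly less than 70% successful
catches are excluded; (2) trials with a click before the target onset or a
total duration strictly above 5.2 s (measured from animation start to
routine end) are dropped; (3) always-on-target losses are accounted.
Reaction times (click minus onset; clickers only) are trimmed by fitting an
intercept-only model with crossed participant and item random intercepts
and removing observations with |standardized residual| > 3; if the crossed
fit fails the function falls back to grand-mean standardization and says
so. Note that trials whose onset exceeds 3.0 s fall for more than 5.2 s, so
unclicked late-onset trials are structurally removed by the duration
filter.

## Statistical models

Decision times (ms) are analysed with linear mixed-effects models with
crossed random effects for participants and items, using ±0.5 contrast
codes where the "more" level is positive: segment present (+0.5) vs deleted
(−0.5); /h/ (+0.5, orthographically coded) vs glottal stop (−0.5); target
predictable, i.e. the competing object unrelated (+0.5), vs a similar
semantic competitor (−0.5). Shorter latencies are better, so facilitatory
effects appear as negative weights.

Model selection starts from the full random-effect structure (slopes for
every within-unit predictor; segment is between-item and gets no item
slope). A fit that errors, triggers optimizer warnings, or is singular
sends the ladder to the next structure: first remove the random-effect
correlations, then remove slopes one at a time — an interaction slope
first, otherwise the slope with the smallest estimated variance. The trail
of attempted structures is returned with the fit. t-tests use Satterthwaite
degrees of freedom (computed by lmerTest and named in the output, since
printed integer dfs do not identify a method by themselves).

Within-participant error bars use participant-centered cell means
(subtract the participant mean, add the grand mean) with Morey's
\(\sqrt{J/(J-1)}\) correction for J conditions and a t quantile on
(participants − 1) degrees of freedom. Participants with incomplete cells
cannot be centered comparably and are dropped from the CI (reported in an
attribute).

### Time-course differences

A model-based smooth analysis of the full time course is out of scope; the
package instead provides a distribution-free stand-in: participant-level
mean trajectories per condition, their difference, and a cluster bootstrap
(resampling participants, B = 2000) of the mean difference curve. Its
significance intervals are not expected to match smooth-based windows
computed on the same data.

The default band is **simultaneous** rather than pointwise: a studentized
max-statistic bootstrap in which the standard error is re-estimated inside
each resample, with the resulting multiplier floored at the pointwise
Student-t critical value. This choice was made because the band's purpose
here is to *call* significant time intervals over 151 correlated grid
points: a pointwise percentile band makes no multiplicity correction and
flags spurious short intervals under the null, while the studentized
max-statistic band holds the family-wise error near the nominal 5% in null
calibrations (naively standardizing by a fixed standard error, without
re-estimation inside resamples, demonstrably under-covers). Pointwise
percentile intervals remain available via `band = "pointwise"`.

## Numerical and degenerate-case choices

* Corridor and catch comparisons are strict or closed exactly as the task
  rules state them; tests probe boundaries with binary-representable
  values, because `0.15 - 0.10 < 0.05` is true in double arithmetic.
* The ≥2 s post-onset guarantee holds exactly in the fall-duration rule;
  recomputing it as a difference of doubles can lose one ulp, so property
  checks allow 10⁻⁹.
* Empty frame lists, empty RT tables, single participants in CI or
  bootstrap computations, unknown factor levels, non-monotone timestamps
  and malformed session files raise classed errors (`mf_*_error`) naming
  the offending element.
* All-equal RT tables have zero residual variance; trimming treats
  non-finite standardized residuals as zero and removes nothing.
* Orientation applied twice, mirroring applied twice, and write-then-read
  of session logs are exact identities (doubles are serialized with 17
  significant digits).

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
cohort simulations derive per-trial child seeds below 2³¹. The test suite
validates decision-time extraction against a brute-force oracle on 10⁴
random state strings, corridor containment over 10⁴ seeded trials,
mirror-invariance of decision times end-to-end over 200 trials at mixed
frame rates, and parameter recovery and null calibration with 20 replicates
of 40 participants × 96 trials each — the full study scale, chosen so that
recovery standard errors (~8–10 ms) are comparable to those reported for
real cohorts of this size.

## Known limitations

* The agent model is deliberately thin; recovery results are stated
  relative to its tracking lag and noise parameters, which real data cannot
  identify separately from commitment.
* The always-on-target loss rate and error rate are controlled by
  `guess_prob` alone; real participants presumably mix strategies within a
  session.
* The duration filter interacts with the onset distribution (late-onset
  unclicked trials are always "slow"); analyses of the filter's behaviour
  should hold onsets fixed.
* The bootstrap time-course band assumes exchangeable participants; items
  are not resampled.
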