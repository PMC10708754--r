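---
title: "Simulating and analysing EDA-triggered experience sampling"
author: "edaprompt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing EDA-triggered experience sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edaprompt)
```

## The problem

Ambulatory emotion research increasingly pairs experience-sampling
prompts with a wrist-worn electrodermal activity (EDA) sensor: skin
conductance, in microsiemens (µS), indexes sympathetic arousal through
sweat-gland activity, and a prompt sent *when arousal rises* can catch
emotional episodes that random prompts miss. The design `edaprompt`
models combines both sampling modes over a ten-day family deployment:
four random prompts per day inside study hours (weekdays 16:00–20:00,
weekends 10:00–18:00, avoiding school hours), plus prompts triggered
whenever EDA exceeds a calibrated resting baseline by a fixed
fraction, capped at four per day.

Evaluating such a pipeline on human data alone is circular: the
trigger algorithm defines which moments get surveyed, so there is no
ground truth for what it should have caught. The package therefore
treats the *synthetic generator as a first-class instrument*: every
stage runs against signals whose arousal episodes, phasic events and
artifacts are known exactly, so detector sensitivity, scheduler
guarantees and analytic formulas can all be verified.

## The generative signal model

A member-day stream is built in four layers, all at 4 Hz:

1. **Tonic level.** The resting skin-conductance level is the
   profile mean plus a mean-reverting AR(1) drift,
   $d_t = \phi\, d_{t-1} + \varepsilon_t$ with
   $\phi = e^{-\Delta t / 120\,\mathrm{s}}$ (a two-minute correlation
   time) and stationary standard deviation `tonic_drift_sd`, clipped
   at 0 µS. Default profile means sit within the 0–2 µS resting range
   (mother 1.0, father 0.9, child 1.2 µS).
2. **Arousal episodes** multiply the tonic level by
   `level_multiplier`, ramping linearly over `ramp_s` at onset and
   offset. Episodes are *multiplicative* so that "a 20% rise over
   baseline" is well defined whatever the member's resting level —
   the same convention the trigger threshold uses.
3. **Phasic SCRs.** Spontaneous skin-conductance responses are
   biexponential bumps,
   $k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ with
   $\tau_r = 0.75$ s and $\tau_d = 2$ s (typical SCR morphology),
   normalised so the discrete peak equals the event amplitude. The
   kernel is normalised on the *sampling grid* rather than at the
   continuous-time peak so that an event of amplitude $a$ raises the
   sampled maximum by exactly $a$; amplitudes are drawn from
   0.05–0.3 µS, the usual range for non-specific SCRs. Rates default
   to 1.5/min (adults) and 2/min (children).
4. **Motion artifacts.** Brief (0.25–2 s) half-sine spikes of random
   sign at a Poisson rate, clipped at 0 µS, with ground-truth onsets
   returned; children default to a higher rate (3/h vs 2/h).

### A deliberate coupling: drift scale vs detection margin

The default `tonic_drift_sd` of 0.0125 µS (1.25% of a 1 µS tonic
level) is chosen by a margin argument, not fitted to anything. A
ground-truth episode at multiplier 1.25 clears the 20% trigger
threshold only while the drifted tonic level stays above
$1.20/1.25 = 96\%$ of the calibration baseline. With a 3-sd drift
excursion of 3.75% the margin is preserved, so every injected ≥ 25%
episode of ≥ 60 s is recoverable — which is what makes the generator
usable as a detector test bed. Real ambulatory EDA drifts far more
than this (posture, temperature, electrode hydration); the generator
intentionally under-represents that nonstationarity, and passing
recovery tests therefore say nothing about detection performance
under real-world baseline wander. The same applies to artifacts: the
half-sine spike model is a placeholder for the rich morphology of
real motion noise.

## The deviation engine

The baseline marker is the arithmetic mean of the 3-minute
calibration recording (720 samples at 4 Hz, half-open window). There
is deliberately *no* within-day re-baselining: the design calibrates
once at orientation, and the engine follows it.

Detection runs in one forward pass over the smoothed signal
(centred 5-s moving average, truncated at edges): a trigger fires at
the first sample where the signal has been at or above
$(1+\theta)\times\text{baseline}$ continuously for the sustain time,
then enters a refractory period. Decisions at time $t$ use only
samples up to $t$; the centred smoother adds a fixed half-window
latency (2.5 s), which we accept for its phase-free noise reduction.

Parameter choices, with the reasoning:

| parameter | default | why |
|---|---|---|
| `threshold_fraction` | 0.20 | the operative deviation criterion; 0.15 (the literature benchmark) remains available via configuration |
| `smooth_window_s` | 5 s | suppresses sample-level noise without blunting minute-scale episodes |
| `sustain_s` | 30 s | phasic discrimination: the smoothed elevation of an SCR — even a cluster of overlapping SCRs — decays within a few seconds, while genuine tonic elevations last minutes. A 5-s sustain was tried first and failed exactly this test: SCR clusters held the smoothed signal above threshold for > 5 s, and the resulting false triggers' refractory periods masked real episodes. |
| `refractory_s` | 900 s | one trigger per survey response window; prevents notification pile-up |
| `daily_cap` | 4 | participants should not be overwhelmed; the cap counts notifications sent, not surveys completed, and resets at each day's window start |

Two numerical details matter. First, the threshold comparison uses a
relative tolerance of $10^{-9}$: a step of *exactly*
$(1+\theta)\times$ baseline must trigger, but cumulative-sum rounding
in the moving average can leave the smoothed value one ulp below the
product. The tolerance is far below any physiologically meaningful
difference and far above double-precision noise. Second, the sustain
condition is "elapsed time at or above threshold ≥ sustain", i.e.
$\lfloor \text{sustain} \cdot f_s \rfloor + 1$ consecutive samples,
so on a constant suprathreshold stream the first trigger lands at
$t = \text{sustain}_s$ exactly.

Deviation notifications are gated to study hours: the design
restricts all surveying to study hours and nothing exempts
event-based prompts from that restriction.

## The scheduler

Study windows divide into `n_intervals` equal **half-open** intervals
$[a, b)$ — the half-open convention means every instant, including
interval boundaries, belongs to exactly one interval, which the tests
verify by exhaustive 1-s membership scan. One prompt is drawn
uniformly per interval. Reminders (one per missed random prompt) are
drawn uniformly between the moment the 15-minute response window has
lapsed unanswered and the interval end; a prompt too close to the
interval end simply gets no reminder. Reminders are not issued for
deviation prompts — the reminder rule belongs to the random schedule.

When random and deviation prompts collide, the merged stream delays
the later prompt to `min_gap_s` (default 120 s) after its
predecessor, applied left to right so all output gaps meet the
minimum; the rule is deterministic so merged schedules reproduce.
Participants cannot tell prompt kinds apart, and `blind_schedule()`
produces the participant-facing view: member, day, time, nothing
else.

Windows are computed as clock times in one fixed time zone (UTC by
default) with **no daylight-saving adjustment mid-study**. A real
deployment crossing a DST transition would shift its windows by an
hour relative to solar time for the remainder; handling that, and
travel across time zones, is out of scope and documented as a
limitation.

## Survey lifecycle and the respondent model

Surveys carry 4 required questions for children and 5 for parents
(the parenting-stress slider); answers validate against the catalog
(13 emotions, 12 activities, 8 child / 9 parent company options,
integer 0–100 sliders). The expiry boundary is *exclusive*: an answer
at exactly +15:00.000 is rejected. Finalization partitions every
instance into exactly one of complete / incomplete (started, some
answers missing) / missed (never started).

The instrument's canonical emotion labels are "relaxed" and
"scared"; report tables sometimes use "content" and "afraid/scared"
for the same options. The catalog keeps the instrument wording and
`format_endorsement(aliases = emotion_aliases())` applies the report
relabelling — the instrument defines the data, reports may relabel.

The simulated respondent answers fully with a kind-specific
probability, partially with `partial_prob` (default 0.05), and
ignores the prompt otherwise. Default full-response probabilities are
the observed per-role completion rates of the deployment this design
comes from: random prompts — mothers .80, fathers .68, children .45;
deviation prompts — .74 / .65 / .77. Default answer-content weights
put most mass on happy/relaxed with a tail of negative emotions, and
favour relaxing / chores / work / TV / eating among activities,
matching the broad shape such family studies report. The model is
deliberately memoryless: no time-of-day effects, no motivation decay
over the study, no dependence of response behavior on the member's
actual arousal — so analytic pipelines can be validated, but nothing
here predicts real engagement dynamics.

## Analytics

- **Engagement** is completes over receives, per member and prompt
  kind; a cell with zero prompts is *undefined*, never zero. An
  overall figure can pool prompts across members or average member
  rates; both are exposed (`pooled_engagement(method=)`) because
  summary conventions differ, and neither is privileged.
- **ICC(1)** is the one-way random-effects estimate
  $(MS_B - MS_W)/(MS_B + (k-1) MS_W)$ with $k = 2$ children per
  family, computed from the mean squares directly. Negative
  estimates are reported as computed (they are informative about
  within-family disagreement) and banded "lack"; bands follow the
  .31/.51/.71/.91 cut points, and sibling aggregation (per-family
  child mean) fires iff ICC(1) ≥ .51. Zero total variance is
  undefined and flagged.
- **Paired comparisons** use the paired *t* with sample-sd
  differences and Cohen's $d_z = \bar{d}/s_d$. This is stated
  prominently because pooled-SD variants of Cohen's *d* give
  systematically different numbers; $d_z$ is the quantity the paired
  *t* statistic scales, $t = d_z\sqrt{n}$. Identical vectors return
  $t=0, p=1, d_z=0$; constant nonzero differences are flagged rather
  than reported as infinite. *p* values are two-sided throughout.
- **Endorsement tables** report label percentages per role × prompt
  kind among answered surveys; zero counts render as "-", columns
  sum to 100 within rounding.
- **USE subscales**: ease-of-use is the mean of 9 of its 11 items
  (items 7–8 excluded for poor factor loadings); satisfaction the
  mean of its 4. Missing items fall back to the available-item mean
  with a flag.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and restores the
global RNG state on exit; a run configuration derives per-member and
per-day seeds from one master seed, so a manifest (config hash plus
seeds) reproduces any run byte for byte.

The shipped verification uses sizes chosen to make the checks sharp
yet quick: 1,000 seeded scheduler days; 100 random streams for the
streaming-vs-offline detector equivalence; 20 sessions × 3 injected
25% episodes for sensitivity; 10,000 prompts for engagement recovery
at a known response probability (binomial sd ≈ 0.4 percentage
points, so recovery within ±1 point is a ~2.5-sd check); 11 families
for the sibling-agreement demonstration, matching the deployment
scale. The default end-to-end study (4 members × 10 days ≈ 2.8
million samples) runs in a few seconds.

In the episode-recovery experiment the injected episodes are spaced
beyond the refractory period; the generator's random episode draw
enforces the same minimum spacing so that each drawn episode is
independently detectable. With roughly three drawn episodes per day
and the daily cap of four, emitted deviation prompts settle near two
per member-day — the load the real deployment observed.

## Known limitations

- Tonic drift is intentionally small relative to the detection
  margin (see above); real baseline wander would erode sensitivity
  and the package makes no claim there.
- One EDA channel only; no photoplethysmography, temperature or
  accelerometry, so artifact detection cannot be cross-validated
  against movement.
- The respondent model is memoryless and context-free.
- Fixed-zone clock windows; no DST or travel handling.
- No tonic/phasic decomposition (deconvolution) — the trigger
  operates on the smoothed composite signal, as the deployed system
  did.
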