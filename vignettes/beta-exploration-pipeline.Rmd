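---
title: "Methods: beta-band dynamics of explorative choice, end to end on synthetic MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-band dynamics of explorative choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What this package computes

`betaxplore` re-implements, as a tested pipeline over purely synthetic data,
a sensor-level analysis of beta-band (16–30 Hz) MEG power during explorative
versus exploitative decisions in a two-alternative probabilistic reward
task. The pipeline has five stages:

1. **Task and agent simulation** — six blocks of 40 trials; in each block one
   option yields the better outcome with probability 0.7 (0.6 in block 6),
   the other with 0.3 (0.4). Outcome sequences are pre-built quasirandomly
   with exact per-block gain counts and a cap on runs of identical outcomes.
   A two-phase agent (learning, then stationary preference with isolated
   explorative lapses) produces choices and log-normal response times.
2. **Trial taxonomy** — the learning criterion (four consecutive
   advantageous choices, then strictly more than 65% advantageous choices to
   the end of the block), the four-level choice-type factor (HP, pre-LP, LP,
   post-LP), current/previous feedback factors, and RT-based exclusion
   (retain 300–4000 ms inclusive).
3. **Synthetic epochs** — response-locked multichannel segments
   (−1750…2750 ms at 300 Hz, 102 combined planar-gradiometer-like sensors on
   a unit-disc layout) whose beta amplitude envelopes carry configurable
   condition-dependent ERD/ERS effects, plus fixation-locked baseline
   epochs for HP trials.
4. **Beta power** — DPSS multitaper band power (16–30 Hz in 2-Hz steps,
   500-ms windows, time-bandwidth 4, 25-ms steps), decibel transform, and a
   fixed baseline per subject and sensor taken from the −350…−50 ms window
   of fixation-locked HP epochs.
5. **Statistics** — stage one: 200-ms frame averaging (17 frames), per-cell
   mixed models `beta ~ ChoiceType * Feedback + (1|Subject)`, Benjamini–
   Hochberg FDR over the 17 × 102 grid, persistence/neighbour cluster rules,
   ERD/ERS sign splitting; stage two: pooled-window mixed models with Tukey
   HSD contrasts, an RT model, a beta~RT regression, previous-feedback
   interactions and the LP→post-LP cross-trial regression.

## The mixed-model engine

Every model in the pipeline is a linear mixed model with a single random
intercept per subject. Rather than depending on `lme4` at runtime (and
paying its cost ~5,000 times per screen), the package profiles the REML
criterion over the variance ratio λ = τ²/σ² directly: with one grouping
factor the marginal covariance is block diagonal, so the criterion, the GLS
fixed effects and their covariance reduce to per-subject sufficient
statistics, and one fit is a one-dimensional optimization over λ. The test
suite verifies the engine against `lme4` (coefficients, residual and
intercept variances, fixed-effect covariance) to ~1e-6.

Fixed effects are tested with Type-III-style Wald F statistics under
sum-to-zero contrasts. The denominator degrees of freedom use a
between-within approximation, `n − p − (n_subjects − 1)`; the
Kenward–Roger/Satterthwaite machinery was considered out of proportion for
this design (thousands of single-trial observations per model, where all df
approximations converge). Post-hoc contrasts are Tukey HSD on estimated
marginal means: reference-grid cell predictions averaged with equal weights
over the factors not in the family, standard errors from the fixed-effect
covariance, and p-values from the studentized range distribution over the
family of k means. Fit failures in the mass screen (e.g. rank deficiency)
are recorded as p = 1 with a diagnostic flag, never dropped.

Whether the original analysis used Wald F or likelihood-ratio tests is not
recoverable from its description; Wald F is the default here and is what
the acceptance properties exercise.

## The synthetic world and its defaults

Everything downstream is driven by the generator, so its defaults *are* the
stated experimental world:

* **Task**: 6 blocks × 40 trials; schemes (−20/+20, 0/+20, −20/0, +20/+50,
  −50/−20, −20/+20 at 0.6/0.4), one of the three permitted counterbalancing
  orders per subject; outcome run cap `max_outcome_run = 3` — the mildest
  constraint consistent with "prevent multiple successive repetitions" (the
  original cap is unpublished; it is configurable).
* **Agent**: stationary P(advantageous) = 0.90 after a learning phase of
  mean ~8 trials; explorative choices isolated (never two in a row) by
  default. Log-RT means by context: HP `log(650)`, pre-LP and post-LP
  `log(780)`, LP `log(950)` (ms), SD 0.35 — invented values reproducing the
  qualitative ordering LP > pre-LP ≈ post-LP > HP well inside the
  300–4000 ms retention window.
* **Sensors**: 102 points on a sunflower spiral over the unit disc;
  neighbour graph by distance threshold, swept upward until every sensor has
  ≥ 2 neighbours; disjoint angular/positional region masks `anterior`,
  `posterior`, `left_central`.
* **Signals**: per sensor, a 16–30 Hz Gaussian carrier (band-limited in the
  frequency domain — filtered noise, not sinusoids, so the multitaper stage
  sees realistic spectral leakage) with a time-varying amplitude envelope,
  plus broadband 1/f noise whose beta-band power is 5% of the carrier's
  baseline beta power, plus a log-normal per-subject amplitude factor
  (SD 0.2) that the dB baseline must absorb. Scaling the envelope by
  `10^(Δ/20)` moves measured beta *power* by Δ dB; with the 5% noise floor
  the measured change tracks the injected change to well within 0.2 dB over
  the default magnitudes.
* **Effects** (invented magnitudes; the literature source prints figures,
  not numbers): decision ERD −1.5 dB (LP −2.25 dB) over
  posterior + left-central sensors; early feedback ERD −1.0 dB (LP
  −1.75 dB) over posterior sensors; late anterior ERS +0.6 dB for HP gains
  and losses, +0.25 dB for pre-LP, for LP **losses only** (+0.6 dB, with LP
  gains followed by −0.9 dB suppression below baseline), and for post-LP
  stronger after losses (+0.6) than gains (+0.2). A decision-window RT
  coupling of −2.0 dB per log-RT unit is on by default; previous-feedback
  and LP→post-LP cross-trial couplings exist but default to zero and are
  switched on by the tests that probe them.

Two generator choices deserve their rationale spelled out. First, each
effect's *injected* time window extends beyond the *analysis* window that
probes it (e.g. the decision ERD spans −1300…100 ms, probed at
−900…−300 ms). This mirrors the real phenomenon — the analysis windows were
originally chosen inside longer-lasting effects — and it matters
numerically: the 500-ms multitaper support would otherwise smear every
estimate with pre/post-effect baseline and attenuate recovered magnitudes
and the RT slope by ~30%. Second, the −0.9 dB LP-gain suppression (the one
magnitude with real structural freedom) was fixed by an a-priori power
calculation: LP-gain trials are ~3% of the data, and the loss−gain spread of
1.5 dB is what gives the per-cell interaction test power > 0.999 at the
Benjamini–Hochberg threshold at the 20-subject acceptance scale. Neither
value was iterated against test outcomes.

What the generator does **not** emulate: alpha-band activity and its
possible bleed into beta, artifacts (ocular, myogenic, cardiac), sensor
noise correlations, 204-channel raw gradiometer geometry (generation is at
combined-sensor level; pair combination is exercised separately), source
geometry, and any reinforcement-learning structure in the agent. A green
recovery test therefore establishes that the *pipeline* recovers what was
injected — not that the physiological claims hold, and not that the method
would survive real artifact regimes.

## Numerical choices

* **Multitaper**: `time_bandwidth = 4` is window length × full smoothing
  bandwidth (the MNE reading), so 500 ms gives half-bandwidth NW = 2,
  `4 − 1 = 3` tapers and the printed 8 Hz smoothing. DPSS tapers come from
  the classical tridiagonal eigenproblem (verified against `scipy` to
  machine precision in development; concentration checked in tests).
  Output times lie on the absolute 25-ms lattice; at 300 Hz the window
  centre can fall between samples, and the window start is rounded (≤1.7 ms
  jitter against a 25-ms step). Times whose window would cross an epoch
  edge are `NA`, never zero-padded; the first/last 250 ms of each epoch are
  therefore invalid by construction and all analysis windows keep clear of
  them.
* **Pair combination before the log**: linear power is summed within a
  sensor pair first, then dB-transformed — summing decibels is not
  physically meaningful. The original description is ambiguous on the
  order; this is the physically defensible reading.
* **dB floor**: log of non-positive power is floored at a configurable
  epsilon (default 1e-300) with a warning.
* **Frames**: "consecutive 200-ms windows centred on −800…2400 ms" tile
  −900…2500 ms; each frame averages the 8 half-open 25-ms lattice points
  `[start, start + 200)`, so frames are disjoint and use every lattice
  point exactly once.
* **>65%** is read strictly (`> 0.65`), and the post-criterion denominator
  includes RT-excluded trials (performance is a property of behaviour, not
  of the analyzable epoch set). The 65% rule's binomial rationale is
  verified by exact tail summation in the acceptance suite.
* **Cluster rules**: persistence requires significance in *every* frame of
  the window; neighbour pruning (< 2 significant neighbours) is a single
  simultaneous pass, not an iteration to fixed point — the literal reading
  of the rule. The ERD/ERS split tests subject-level window means against
  zero (two-sided t, p < 0.05, uncorrected), matching the grand-average
  framing of that step.
* **Previous feedback** comes from the chronologically previous trial even
  if that trial was itself excluded — the participant experienced it. It is
  `none` only at block starts and never crosses blocks.
* **Eq-(7)-style pairing**: each LP-loss trial is paired with the
  immediately following post-LP trial within subject and block (by the
  taxonomy, post-LP follows LP directly). Both a trial-level mixed
  regression and a subject-aggregate OLS mode are provided; the original
  aggregation level is ambiguous and neither is asserted as "the" original.

## Reproducibility and scale

A single master seed drives everything: stage seeds derive deterministically
from it, cross-trial latents are seeded independently of carrier noise, and
two runs from one master seed produce byte-identical serialized results
(this is an acceptance criterion). The acceptance recovery run uses 20
subjects × 6 blocks at the full 102-sensor layout (~9 minutes on one CPU);
FDR calibration runs 200 replicate null screens at a reduced 6 × 20 grid
with 20 subjects × 20 trials, generating frame-grid values directly from
the null model rather than synthesizing spectra 200 times. Epoch synthesis
and spectral estimation are chunked per subject, bounding memory at well
under 1 GB at acceptance scale.

## Known limitations

* Only a random-intercept-per-subject structure is supported — exactly what
  the analyses specify, but nothing more (no random slopes, no crossed
  random factors).
* The between-within df approximation is slightly conservative for small
  cells; at single-trial sample sizes the effect is negligible, and the
  Tukey adjustment inherits it.
* The agent has no learning dynamics (choices before the criterion are
  coin flips); analyses never see those trials, but learning-curve
  questions cannot be asked of this generator.
* Numeric F/R² values from the original study are data-dependent and are
  not reproduction targets; the pipeline reproduces parameter identities,
  oracle equivalences and injected-effect recovery, nothing else.
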