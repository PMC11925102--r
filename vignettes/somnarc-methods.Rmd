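---
title: "somnarc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnarc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnarc)
library(dplyr)
```

somnarc analyzes rodent sleep studies in which the home cage is rocked
laterally (vestibular stimulation, here ±20 mm at 1.0 Hz) during the rest
phase to promote NREM sleep. It covers the full measurement chain of such a
study: epoch-wise hypnograms and their architecture metrics, per-epoch EEG
spectra and band summaries, motion-based sleep inference for chronic
(unimplanted) monitoring, longitudinal block-design summaries, behavioral
and densitometry scoring, and a thin statistical comparison layer. Because
animal-level recordings are not generally available, the package ships a
synthetic-data generator that reproduces the statistical structure every
downstream stage assumes, so the whole pipeline is testable end to end.

## The vigilance-state generator

`simulate_hypnogram()` draws a 24-h sequence of wake (W), NREM (NR) and REM
(R) states on a 4-s epoch grid from a semi-Markov chain: dwell times are
geometric at epoch resolution with phase-specific means, and on leaving a
state the next state follows a conditional transition matrix. This is the
simplest process that reproduces bout-duration histograms of rodent sleep;
no claim is made that it captures longer-range dependencies (see
*Limitations*). Two structural constraints are enforced: REM is entered
only from NREM, and the dark-period dynamics are identical whether or not
the platform is scheduled, because rocking runs only during the light
period.

Rocking acts multiplicatively on the wake-to-NREM transition hazard — and
on nothing else. The motivation is empirical: rocking increases the number
of short-to-medium sleep episodes, i.e. sleep *entries*, rather than
stretching consolidated episodes, so boosting the exit hazard of wake into
NREM is the minimal mechanism with that signature. The gain is

\[ g(t, c) = 1 + A\,e^{-t/\tau_\text{within}}\,e^{-c/\tau_\text{across}}, \]

where \(t\) is the accumulated stimulation time (hours) within the current
cycle — hours since lights-on plus 12 h for every prior stimulation day of
that week — and \(c\) is the zero-based cycle index. The separable
exponential form is a modeling choice: only the qualitative decay
(within-session, across days, across cycles) is empirically established,
not its functional form. Making \(t\) cumulate across the days of a
stimulation week (rather than resetting each morning) is what lets a single
time constant produce both the within-session decline and the day-1 >
day-7 ordering that block-design studies report. Habituation and disease
progression are deliberately conflated in \(\tau_\text{across}\): the data
cannot separate them, and neither does the generator.

Hazards are held piecewise-constant over 30-min blocks; geometric dwell
draws are truncated at block boundaries and resumed, which is exact for a
memoryless dwell process, so the only approximation is that the gain decays
in 30-min steps rather than continuously.

### Default study conditions

Defaults are fixed once, as the conditions the package emulates, and are
not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| epoch length | 4 s | standard rodent scoring epoch |
| light dwell means (W/NR/R) | 96/160/64 s | mouse light-period bouts of a few minutes; yields ~35% W, ~59% NR, ~6% R |
| dark dwell means (W/NR/R) | 400/128/56 s | wake-dominated dark period (~74% W) |
| NR→R probability (light/dark) | 0.25 / 0.20 | REM entries every ~4th NREM bout |
| rocking gain \(A\) | 1.5 | early-cycle light-NREM gain of ~1.5 h, a strong but plausible first-day effect |
| \(\tau_\text{within}\) | 18 h | clear decline within a 12-h session and near-baseline by day 7 (72+ h of stimulation) |
| \(\tau_\text{across}\) | 3 cycles | pronounced early cycles, weak ninth cycle |
| rocking frequency | 1.0 Hz | platform rate |
| entrainment factor | 2 | the vestibular stimulus is encoded at about twice the platform rate, so entrained NREM oscillations sit near 2 Hz |
| baseline NREM delta peak | 3.0 Hz | unstimulated delta peak; the 2 Hz peak is the entrainment effect |
| EEG sample rate | 128 Hz | integer samples per 4-s epoch, Nyquist above the 40 Hz band edge |
| NREM/REM oscillation amplitude | 8 / 5 (a.u., noise scale 1) | in-band SNR ≈ 3.9 for the NREM oscillation |
| wake movement rate | 6 events/min | mice move frequently when awake |
| wake quiet-gap cap | 20 s | must stay < 40 s; bounds the boundary error of the immobility rule |
| sleep twitch rate | 0.2 events/min | occasional movement during sleep |

## EEG synthesis and spectral metrics

`simulate_eeg()` builds each epoch as band-limited \(1/f^a\) background
noise plus a state oscillation: NREM delta at 3.0 Hz, replaced by
`entrain_factor * rocking_freq` = 2.0 Hz in rocking-on epochs; REM theta at
7 Hz; wake is low-amplitude background only. Oscillation phase is
randomized per epoch and no amplitude continuity is enforced at epoch
boundaries — all spectral metrics are epoch-local, so discontinuities are
harmless, and no biophysical (e.g. neural-mass) model is attempted.

`epoch_psd()` computes one periodogram per 4-s epoch over the full epoch
window. A 4-s window has 0.25-Hz native resolution, which is exactly the
reporting grid of the band metrics, so no within-epoch (Welch) averaging is
used; bins are half-open \([f, f+0.25)\) from 0.25 to 30 Hz, and powers are
scaled so their sum matches the band-limited signal variance (Parseval).
The band metrics are then: SWA = mean NREM power over \([0.5, 4)\) Hz per
epoch; beta = mean NREM power over \([15, 30)\) Hz; SWE = running
cumulative sum of per-epoch NREM SWA over light-period epochs, so its final
value equals the sum of the contributing SWA values exactly. The
"between X and Y Hz" band wording leaves the boundary convention open;
half-open intervals are used everywhere in this package, including the
ZT0–ZT12 light period (an epoch starting exactly at ZT12 is dark).
Artifact rejection is out of scope. SWE units are arbitrary-power × epoch,
so only within-animal comparisons are meaningful. The normalization behind
"normalized beta power" plots is not standardized across labs;
`normalize_band()` implements a plain ratio and the caller chooses the
baseline.

## Architecture metrics

Episodes are maximal same-state runs. The duration filter is read
literally from its clinical wording: episodes must be *longer than* 8 s
(strict), so a 2-epoch (8-s) NREM run fails and a 3-epoch (12-s) run
passes. REM epochs terminate a NREM episode; no NREM–REM merging is done.
Episode-duration histograms use half-open 20-s clusters with an overflow
cluster at 240 s.

A brief arousal is a wake run strictly shorter than 16 s (≤ 3 epochs)
whose *immediately flanking maximal NREM runs* each last at least 20 s —
cumulative flanking NREM does not qualify, and REM-flanked wake never
counts. A 20-s flank necessarily passes the 8-s episode filter, so the two
definitions are consistent. An arousal straddling the light/dark boundary
is assigned to the period containing its first wake epoch.

## Motion-based sleep inference

`infer_sleep()` implements the immobility rule: every maximal run of
sub-threshold motion samples lasting ≥ 40 s is sleep in full; everything
else is wake. The movement threshold is a required explicit parameter, not
auto-estimated — camera sensitivity varies, which is also why per-day
metrics are baseline-normalized before pooling. The rule's inherent
failure mode, quiet wakefulness longer than 40 s being misread as sleep,
is not corrected; in the generator its frequency is controlled by the wake
quiet-gap cap. Concordance against a hypnogram resamples the inferred
series to the 4-s grid by strict majority vote and maps NREM∪REM to sleep.
On default synthetic cohorts this concordance is ~95–96%, consistent with
the ~93% reported when the method was validated against EEG in implanted
mice. The fragmentation index counts sleep→wake transitions per hour
(wake→sleep transitions are not counted; a transition belongs to the
period containing its wake-onset sample).

`normalize_to_baseline()` divides each day's value by the mean over the
(≥ 3) baseline days, so the baseline mean maps to exactly 1.0, and
`build_matrix()` averages per-mouse metrics into the day × cycle matrix
with day and cycle profiles; missing days (camera dropout) are `NA` and
excluded from means, never zero-filled.

## Statistical layer

Paired/unpaired contrasts and (repeated-measures) ANOVA delegate to
`stats::t.test` and `stats::aov` behind a thin contract — the package
asserts shape and p-validity, and its tests cross-check the t statistic
against the textbook formula. Sidak correction is authored here:
\(p_\text{corr} = 1 - (1-p)^m\), computed via `expm1`/`log1p`. For the
bin-wise spectral test, \(m\) defaults to the number of bins actually
tested in the requested range (14 for \([0.5, 4)\) at 0.25 Hz), with an
override because published degrees of freedom for such insets are
sometimes ambiguous about the family size; no guess is recorded as truth.
All tests are two-sided and parametric; no normality checks are performed.

## What the generator does and does not establish

Passing tests on synthetic cohorts shows that the *analysis* is correct
under the generative assumptions: geometric dwell times, separable
habituation, epoch-local spectra, state-conditional motion statistics.
Real recordings violate several of these — bout durations are
heavier-tailed than geometric, sleep pressure couples successive days,
EEG spectra drift with age and pathology, and motion artifacts are not
i.i.d. — so concordance or power numbers obtained here do not transfer to
real data as guarantees. The generator also makes no attempt to model
amyloid/tau dynamics; disease progression enters only through the
phenomenological across-cycle decay.

## Problem sizes

The bundled checks run at the scales the analyses are designed for: 8
simulated mice × 24 h for the motion-rule validation, 500 entrained NREM
epochs for the spectral peak, ≥ 200 Monte-Carlo days per arm for the
habituation ordering, 10,000 random sequences for the exact brute-force
equivalences, and 1000 null simulations for familywise-error control of
the bin-wise test.

## A worked pass through the pipeline

```{r example}
cfg <- generator_config()
hyp <- simulate_hypnogram(cfg, design_day(rocking = TRUE), seed = 1)
state_amounts(hyp, "light")

trace <- simulate_motion(hyp, cfg, seed = 2)
sw <- infer_sleep(trace, min_immobility_s = 40)
c(sleep_min = sleep_amount(sw, "light"),
  frag_per_h = fragmentation_index(sw, "light"),
  concordance = concordance(sw, hyp))

nrem <- hypnogram(rep("NR", 100), rocking_on = TRUE)
sf <- epoch_psd(simulate_eeg(nrem, cfg, seed = 3), nrem)
spectral_peak(state_spectrum(sf, nrem, "NR"), range = c(0.5, 4))
```
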