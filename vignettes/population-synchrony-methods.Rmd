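---
title: "Methods: population synchrony and tuning analysis of dorsal horn recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population synchrony and tuning analysis of dorsal horn recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesync)
```

## What the package computes

`spikesync` analyses populations of simultaneously recorded spinal dorsal
horn (DH) units responding to mechanical stimulation of the hindpaw skin:
force-controlled 500 ms indentation steps at innocuous forces (1–75 mN),
each preceded by a 1.5 s baseline, and minutes-long gentle brush epochs.
The analyses are organized around one question: how precisely is spiking
coordinated across the population, and how does that coordination — rather
than single-unit rate — change in neuropathic states?

The stages are:

* **Tuning** — peristimulus time histograms (PSTHs, 10 ms bins), evoked
  rates in three windows (ON: 0–50 ms after step onset; OFF: 0–50 ms after
  offset; sustained: the 200 ms before offset), bootstrap response
  thresholds, and per-minute brush response maxima.
* **Correlations** — population coupling (spike-triggered population rate
  at zero lag against a shuffled null), pairwise lag-0 synchrony and
  cross-correlograms, trial-by-trial noise correlations, and PSTH-based
  signal correlations; all stratifiable by recording depth (superficial
  `[0, 240)` µm vs deep `[240, 620]` µm).
* **Timing** — first-spike latency via a shuffled-null crossing and jitter
  as the across-trial SD of first-spike latencies.
* **Signals** — LFP power spectra and relative gamma (30–80 Hz) power,
  extracellular waveform features with k-means clustering (k = 3), and
  opto-tag classification.
* **Behavior** — dynamic brush allodynia scoring.

Because the in-vivo recordings this kind of study uses are not publicly
deposited, the package pairs every stage with a synthetic session
generator whose ground truth makes the estimators testable by parameter
recovery. The test suite and the acceptance script are entirely
recovery- and property-based.

## The generative model

`simulate_session()` draws, for unit $i$ on trial $t$ at force $F$, a
private inhomogeneous Poisson process with rate

$$\lambda_i(\tau) = g_t\,\bigl[b_i + \mathbf{1}\{F \ge \theta_i\}\, w_i(F)
\bigl(A^{on}_i\,\alpha_{on}(\tau) + A^{sus}_i\,\mathrm{box}(\tau) +
A^{off}_i\,\alpha_{off}(\tau - 0.5)\bigr)\bigr]$$

where $\tau$ is time from step onset, $b_i$ is the baseline rate (Hz),
$\theta_i$ the force threshold (mN), $\alpha$ are alpha kernels with unit
peak (time constants 10 ms by default), and `box` spans the step. Sampling
uses thinning, which is exact. On top of this:

* **Millisecond synchrony** is injected by a *population event* train
  (Poisson, at a configurable rate during response windows, spontaneous
  blocks and brush epochs). At each event, unit $i$ emits one spike with
  probability $p_i$ at the event time plus Gaussian jitter of SD
  $\sigma_{sync}$ (default 1 ms). This gives exact, independently tunable
  per-unit coupling ($p_i$) and timescale ($\sigma_{sync}$), unlike a
  common Gaussian latent. Conditional on the event train, units are
  independent, so closed-form co-spike expectations are available as test
  oracles.
* **Slow shared variability** is a per-trial lognormal gain $g_t$ with
  mean 1 and configurable CV, applied to the whole trial window including
  the baseline. For two units with rates $\mu_i,\mu_j$ counted over
  windows of length $T$, the expected count correlation is
  $\rho_{ij} = cv^2\mu_i\mu_jT^2 / \sqrt{(\mu_iT + cv^2\mu_i^2T^2)(\mu_jT
  + cv^2\mu_j^2T^2)}$ (`expected_shared_gain_noise_r()`), the oracle for
  the noise-correlation tests.
* **Tuning similarity** mixes each unit's force-tuning vector from a
  shared saturating template and a private random template with weight
  $\rho$; $\rho = 1$ gives identical tuning, and an explicit
  `tuning_weights` matrix can override the mix (used to build orthogonal
  tuning pairs in tests).
* **First-spike latencies** can be forced: when a trial's first evoked
  spike would arrive later than a draw from $N(\mu_i, SD_i)$, a spike is
  inserted at that latency. The observed first-spike distribution is
  therefore $\min(\text{Poisson first arrival}, N(\mu_i, SD_i))$ — at low
  baseline rates essentially the Gaussian.

All randomness flows from a single integer seed through named streams
keyed by unit and trial, so enlarging a population or adding trials does
not perturb existing spikes. Merged spike trains are deduplicated at the
50 µs sampling resolution of a 20 kHz recording.

**What the generator does not emulate:** refractoriness, bursting,
non-stationary drift, receptive-field geometry, afferent conduction
classes, true biophysics of presynaptic/feedforward inhibition, and
electrode artifacts. Passing recovery tests therefore demonstrates that
the estimators recover the parameters of *this* phenomenological model,
not that they are robust to every property of real recordings.

## Population coupling

Single-unit activity is summed into a population count vector at 1 ms
resolution (3 and 10 ms variants for the timescale sweep) over an epoch —
by default the union of each trial's ON, OFF and sustained windows. For
each unit, the spike-triggered population rate at zero lag is the mean
count of *other* units' spikes in the trigger unit's spike bins,
converted to Hz. The null redraws the trigger unit's spike times
uniformly over the epoch, holding the rest of the population fixed, 100
times; the reported coupling is observed minus the shuffle median
("normalized population firing rate").

Design choices worth stating:

* *Which trains are shuffled.* Randomizing only the trigger unit keeps
  the population structure intact and makes the null interpretable as
  chance coupling of this unit to the observed population;
  `shuffle_all = TRUE` gives the alternative. The shuffle count (100) is a
  default, not a quoted convention.
* *Units.* Coupling is reported in Hz at lag 0 exactly (counts per
  trigger bin divided by the bin width), with no averaging window around
  zero.
* *Stratification.* For depth-stratified coupling both the trigger units
  and the summed population are restricted to the stratum, with at least
  5 simultaneous units required; the superficial stratum is the half-open
  interval `[0, 240)` µm so a unit exactly at the boundary is assigned
  deterministically.
* *A calibration caveat.* For independent units the estimator is unbiased
  (verified by simulation), but couplings of the units of one session are
  weakly positively correlated, because chance clustering of the realized
  summed rate raises every unit's observed value together and the
  trigger-shuffle null cannot absorb it. The across-session SD of the
  session-mean null coupling is therefore ~1.5× the naive
  $SD/\sqrt{n}$; with 20 units over 100 s a "mean within 2 SE of 0" check
  fails for roughly one seed in six despite zero bias.

### The bin-size sweep

Expanding the coupling bin from 1 to 3 to 10 ms probes the timescale of a
synchrony difference. Two regimes matter:

* The *raw* (Hz-scale) contribution of millisecond population events to
  coupling falls as $q(\sigma, \Delta)/\Delta$, where $q$ is the
  probability that two event spikes jittered by $\sigma$ land in the same
  bin of width $\Delta$ — with $\sigma = 1$ ms, the 10 ms value is ~36%
  of the 1 ms value. This is bin dilution: the same coincident spikes are
  spread over a 10× longer bin.
* The *standardized* (effect-size) difference between conditions only
  attenuates if coupling variance at coarse bins is dominated by
  something other than the events. In homogeneous simulations with no
  slow shared structure, between-session SD scales with the event
  contribution itself and Cohen's d is flat across bins. With slow shared
  modulation (stimulus-locked co-modulation, shared gain) and
  session-to-session heterogeneity — both prominent in real multi-animal
  recordings — the coarse-bin variance is dominated by the slow
  component, and the standardized millisecond-synchrony difference
  collapses at 10 ms while surviving at 3 ms. The bin-sweep test
  conditions therefore use evoked epochs of stimulus sessions with
  per-session heterogeneity in baseline rates, gain CV and tuning mixing.

## Pairwise correlations

* **Synchrony**: both trains binned at 1 ms over the epoch; `sync_r` is
  the Pearson correlation at zero lag, the CCG the same at lags within
  ±50 ms. Lags never straddle the boundary between epoch windows, so
  evoked-epoch CCGs are pooled over within-window shifts only. Pairs need
  ≥10 spikes per unit; zero-variance vectors return `NA` with a reason.
* **Noise correlations**: Pearson correlation across ≥20 matched windows
  of the two units' spike counts; the default windows are the per-trial
  1.5 s pre-stimulus baselines (the choice between inter-trial baselines
  and a separate spontaneous block is not settled by convention; baselines
  are always available).
* **Signal correlations**: Pearson correlation of trial-averaged
  responses in 50 ms bins, concatenated across forces within the
  indentation class (or the binned brush epoch). The PSTH window is
  configurable; note that including baseline bins adds a shared
  low-activity segment to both profiles and thus a positive offset to the
  correlation — orthogonality statements refer to the configured window.

Pearson is used throughout for consistency; rank alternatives would
change none of the qualitative recovery results.

## Bootstrap response thresholds

The threshold is the smallest force whose trial-mean rate in any of the
three response windows exceeds a bound derived from the unit's own
baseline firing; units that never exceed it have no threshold and are
excluded from tuning summaries.

The obvious implementation — bootstrap the mean of per-trial baseline
rates and take the 97.5th percentile — is badly miscalibrated for this
use: the baseline mean (1.5 s windows, all trials) is an order of
magnitude less variable than a 50 ms window statistic averaged over ~50
trials, so comparing the latter to the former's CI yields per-comparison
false-positive rates near 50%, and essentially every purely spontaneous
unit is assigned a spurious threshold. `detect_threshold()` therefore
resamples the baseline in *window-length segments* (the 1.5 s baseline of
every trial is chopped into 50 ms or 200 ms pieces), simulates the full
family of (force × window) trial-mean statistics under the null, and uses
the $(1-\alpha)$ quantile of the family **maximum** as the bound. By
construction the probability that a spontaneous unit receives any
threshold is $\alpha$ (5%), and recovery of an injected 10 mN threshold
with a 30 Hz ON response over a 3 Hz baseline exceeds 90%. The naive
scheme is retained as `method = "naive"` for comparison.

## First-spike latency and jitter

Per trial, the first spike within a 100 ms search window after onset (a
documented default; the window length is a free parameter) defines the
latency sample. The *cumulative* count of first-spike latencies, in 1 ms
bins, is compared to the same curve computed from per-trial spike trains
redrawn uniformly over (onset − 1.5 s, onset + window], preserving
per-trial counts. The cumulative form is used because its crossing time is
well-defined with sparse counts; a histogram mode is the obvious
alternative and is deliberately not the default.

The band is a **global rank envelope** estimated from the shuffle
ensemble: the per-bin order statistic is chosen so that at most 5% of the
null curves themselves exceed the band anywhere. A pointwise 97.5%
band scanned across ~100 bins is liberal (many correlated comparisons)
and fails the pure-noise calibration; the rank envelope restores it
(`band = "pointwise"` remains available). The latency is the left edge of
the first bin where the empirical curve exceeds the band; jitter is the
SD of per-trial first-spike latencies over trials with a spike, and both
are `NA` when no crossing occurs. At least 50 trials are required.

A consequence of the crossing definition worth knowing: for a Gaussian
first-spike distribution $N(\mu, s)$ the crossing occurs where the
cumulative mass lifts above chance — near $\mu - 2s$ for clean responses
— not at the mean. Recovery tests are written against that oracle.
Background spikes contaminate jitter upward slightly (the observed first
spike is the minimum of the evoked latency and a background arrival).

`classify_optotag()` reuses the same envelope machinery on light-pulse
alignments (10 ms response window, 100 ms pre-pulse shuffle extent, ≥25
pulses per block): a unit is tagged when responsive both before and after
the glutamatergic blocker (direct rather than synaptically relayed), with
median light-evoked latency < 10 ms and jitter ≤ 3 ms.

## LFP spectra

Each channel is low-pass filtered at 250 Hz with an 8-pole Butterworth
filter applied forward and backward (zero phase), and a Welch PSD is
computed: Hann-windowed, mean-detrended segments of a power of two near
2 s with 50% overlap, averaged (segment length and overlap are documented
defaults; none are quoted conventions). Relative band power is the
trapezoid integral over 30–80 Hz divided by the integral over (0, 250]
Hz — the *post-filter* range is the denominator, the natural choice when
the trace has been band-limited to it. The Welch routine is implemented
in the package (~20 lines) because the installed signal-processing
library provides the filter but not Welch averaging.

## Waveforms and clustering

Features per mean waveform: trough-to-peak duration (global trough to the
subsequent maximum), trough-to-peak amplitude ratio, and a
"repolarization slope" defined here as the slope of a linear fit over the
0.5 ms after the peak — "waveform slope" has no unique convention, and
this definition is scale-equivariant (doubling the waveform doubles the
slope and changes nothing else). Features are standardized and clustered
with `stats::kmeans` (k = 3, 20 restarts, best within-cluster sum of
squares); degenerate all-identical inputs short-circuit to a single
flagged cluster.

## Behavior

Dynamic-brush responses are scored 0–3 per stroke (0: none or a fast
lift; 1: sustained lifting ≥ 2 s; 2: lateral kicking/flinching; 3:
licking), in three 3-minute periods. The allodynia score is the mean of
per-period maxima, and a mouse is called allodynic above 1.5. Only the
per-period maximum matters, so unequal trial counts per period are
accepted. Group comparisons default to the rank-sum test (the data are
ordinal or non-normal); a percentile bootstrap of the mean difference is
the alternative.

## Condition presets

`preset_condition()` encodes directional phenotypes against a common
reference (`sham_like`): `sni_like` halves superficial event
participation, reduces sustained amplitude 30% and doubles latency SD;
`pv_silenced_like` raises baseline and evoked rates 30% and halves
participation; `psi_ko_like` raises rates 30%, raises participation 50%
and lowers every threshold by one force step. These magnitudes are
testing conventions, not estimates of biology — the contrast harness
asserts effect *directions* only, never magnitudes, because the
magnitudes in the source recordings are not recoverable at desk scale.
Base parameter draws depend only on the seed, so presets sharing a seed
have matched units.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen to give each check clear power
while staying fast: null-coupling calibration uses 20 units × 100 s;
coupling recovery 20 units × 150 s with event participation split
0.1/0.5; the bin sweep 12 sessions per arm; threshold recovery 100 units
at 50 trials per force with 1000 bootstraps; latency recovery 100 trials
with 100 shuffles; the directional harness 12 sessions per arm with 12
units each. Further numerical conventions: time is float64 seconds
internally (milliseconds only at user-facing boundaries); counting
windows are half-open `(lo, hi]`; bins never straddle epoch-window
boundaries and a trailing remainder shorter than one bin is dropped;
overlapping indentation trials are rejected rather than truncated so the
1.5 s baselines are unambiguous; session files store doubles at full
precision (`%.17g`) so a save/load round-trips exactly.

## Known limitations

* The coupling shuffle null does not absorb session-level chance
  clustering (see the calibration caveat above); comparisons across many
  sessions are unaffected, single-session means of ~20 units carry ~5 Hz
  of correlated uncertainty.
* The latency crossing estimates the lift-off point of the first-spike
  distribution, which for broad distributions is earlier than the mean
  latency.
* Waveform clustering is descriptive; k = 3 is a convention and no
  cell-type claim is attached to cluster labels.
* The simplified opto-tag criterion (envelope responsiveness + latency +
  jitter) replaces published stimulus-associated-latency test statistics;
  it is monotone in the intended direction but not a reimplementation of
  them.
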