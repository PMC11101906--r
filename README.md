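# spikesync

Population-synchrony and tuning analysis for in-vivo multielectrode
recordings of spinal dorsal horn (DH) interneurons under mechanical skin
stimulation, paired with a ground-truth spike-train simulator that makes
every estimator testable by parameter recovery.

Neuropathic pain states can leave single-unit evoked rates largely intact
while degrading the *temporal coordination* of DH populations. Detecting
that requires a specific analysis stack: response windows and bootstrap
thresholds for 500 ms indentation steps (1–75 mN forces, 1.5 s baselines),
population coupling at millisecond resolution against a shuffled null,
pairwise synchrony/noise/signal correlations, first-spike latency and
jitter, LFP band power, waveform clustering, opto-tag classification, and
dynamic-brush allodynia scoring. `spikesync` implements that stack as a
tested R package plus a set of narrative analysis drivers.

## The core statistic

For unit $i$ with spikes binned at width $\Delta$ (1 ms by default) over an
analysis epoch, the spike-triggered population rate at zero lag is

$$\mathrm{stPR}_i(0) = \frac{1}{N_i}\sum_{s \in \text{spikes}_i}
\frac{P_{-i}[b(s)]}{\Delta},$$

where $P_{-i}[b]$ counts all *other* units' spikes in bin $b$. The
reported **population coupling** is $\mathrm{stPR}_i(0)$ minus the median
of the same statistic with unit $i$'s spike times redrawn uniformly over
the epoch (population held fixed, 100 shuffles) — the "normalized
population firing rate". Sweeping $\Delta$ over 1, 3, 10 ms probes the
timescale of synchrony differences. Supporting statistics: lag-0 Pearson
synchrony and cross-correlograms of binned pairs, trial-by-trial spike
count (noise) correlations over matched windows, PSTH (signal)
correlations in 50 ms bins, bootstrap response thresholds (family-wise
calibrated against the unit's own baseline), and a shuffled-null
cumulative-curve crossing for first-spike latency.

## Worked example

Simulate a 16-unit session with injected millisecond synchrony, recover
coupling and a response threshold:

```r
library(spikesync)
out <- simulate_session(
  protocol_spec(trials_per_force = 12),
  population_spec(n_units = 8, b_hz = 5, theta_mN = 10, p_event = 0.3,
                  event_rate_hz = 6, gain_cv = 0.2, latency_mu_ms = 10),
  seed = 42)
s <- out$session
population_coupling(s, seed = 1)[, c("unit_id", "n_spikes", "coupling_hz")]
#>   unit_id n_spikes coupling_hz
#> 1     u01      366    349.7268
#> 2     u02      386    240.9326
#> ...
detect_threshold(s$trains[[1]], s$events, seed = 2)$threshold_mN
#> [1] 10
```

Every unit participates in population events with probability 0.3, so all
units couple well above the shuffle null (hundreds of Hz at 1 ms bins);
the detected threshold equals the injected 10 mN.

The numbered drivers under `analysis/` run the full study on simulated
conditions and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # four condition presets -> session dirs
Rscript analysis/02_tuning.R            # thresholds vs ground truth (97% exact)
Rscript analysis/03_correlations.R      # coupling by condition/stratum/bin
Rscript analysis/04_timing_signals.R    # latency, LFP gamma, waveforms, opto-tags
Rscript analysis/05_behavior_contrast.R # allodynia scores + directional contrasts
```

Representative output (driver 03): mean coupling (Hz, 1 ms bins) is
highest in the presynaptic-inhibition-knockout-like preset (486), reduced
after simulated nerve injury (293 vs 392 in sham), with the superficial
stratum carrying the deficit — the direction pattern the analysis stack
is built to detect.

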