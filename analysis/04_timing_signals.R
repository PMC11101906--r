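#!/usr/bin/env Rscript
# First-spike latency/jitter at 10 and 75 mN, LFP relative gamma power on
# simulated traces, waveform clustering, and opto-tag classification on a
# constructed light-pulse session.

library(spikesync)

seed <- 43
dir.create("results", showWarnings = FALSE)

## latency and jitter: dedicated high-trial sessions (50-trial minimum)
lat_rows <- list()
for (cond in c("sham_like", "sni_like")) {
  sd_lat <- if (cond == "sham_like") 1.5 else 3     # preset latency SDs
  # first spikes come from the forced-latency mechanism (A_on = 0), so the
  # recovered jitter tracks the injected latency SD directly
  o <- simulate_session(
    protocol_spec(forces_mN = c(10, 75), trials_per_force = 60),
    population_spec(n_units = 6, b_hz = 3, theta_mN = 10, A_on = 0,
                    A_sus = 0, A_off = 10,
                    latency_mu_ms = 11, latency_sd_ms = sd_lat),
    seed = stream_seed(seed, cond), condition = cond)
  s <- o$session
  ind <- s$events[s$events$kind == "indentation", ]
  for (f in c(10, 75)) {
    on <- ind$onset_s[ind$force_mN == f]
    for (uid in names(s$trains)) {
      lr <- latency_and_jitter(s$trains[[uid]], on,
                               seed = stream_seed(seed, cond, uid, f))
      lat_rows[[paste(cond, uid, f)]] <- data.frame(
        condition = cond, unit_id = uid, force_mN = f,
        latency_ms = lr$latency_ms, jitter_ms = lr$jitter_ms)
    }
  }
}
lat <- do.call(rbind, lat_rows)
save_results(lat, "results/latency.csv", seed = seed)
cat("Mean latency / jitter by condition (pooled forces):\n")
print(round(do.call(rbind, lapply(split(lat, lat$condition), function(d)
  c(latency_ms = mean(d$latency_ms, na.rm = TRUE),
    jitter_ms = mean(d$jitter_ms, na.rm = TRUE)))), 2))

## LFP: 1/f background with and without an added gamma oscillation
for (g_amp in c(0, 0.5)) {
  x <- simulate_lfp(60, 1000, one_over_f_amp = 1, gamma_hz = 55,
                    gamma_amp = g_amp, seed = stream_seed(seed, "lfp", g_amp * 10))
  r <- lfp_spectrum(x, 1000)
  cat(sprintf("LFP gamma_amp %.1f -> relative gamma power %.3f\n",
              g_amp, r$relative_band_power))
}

## waveforms: two narrow classes and one broad, k-means with k = 3
wf <- simulate_waveforms(40, list(list(trough_to_peak_ms = 0.3),
                                  list(trough_to_peak_ms = 0.5),
                                  list(trough_to_peak_ms = 0.9)),
                         noise_sd = 0.03, seed = stream_seed(seed, "wf"))
feats <- waveform_feature_table(wf$waveforms, wf$fs_hz)
cl <- cluster_waveforms(feats[, 1:3], k = 3, seed = stream_seed(seed, "km"))
agree <- sum(apply(table(cl$cluster, wf$labels), 1, max)) / length(wf$labels)
cat(sprintf("Waveform clustering: %d clusters, label agreement %.2f\n",
            length(unique(cl$cluster)), agree))
save_results(cbind(feats, cluster = cl$cluster, true_class = wf$labels),
             "results/waveforms.csv", seed = seed)

## opto-tagging: one tagged unit (responds pre+post), one relayed unit
pulses_pre <- seq(2, by = 0.25, length.out = 40)
pulses_post <- seq(15, by = 0.25, length.out = 40)
o <- simulate_session(
  protocol_spec(forces_mN = numeric(), trials_per_force = 0,
                n_light_pulses = 0, spont_dur_s = 30),
  population_spec(n_units = 2, b_hz = 4), seed = stream_seed(seed, "opto"))
tagged_times <- sort(c(o$session$trains[[1]]$spike_times,
                       c(pulses_pre, pulses_post) + 30 + 0.004))
net_times <- sort(c(o$session$trains[[2]]$spike_times, pulses_pre + 30 + 0.006))
t_stop <- 30 + max(pulses_post) + 2
tr_tag <- spike_train("tagged", tagged_times, t_stop)
tr_net <- spike_train("relayed", net_times, t_stop)
for (tr in list(tr_tag, tr_net)) {
  r <- classify_optotag(tr, pulses_pre + 30, pulses_post + 30,
                        seed = stream_seed(seed, "tagtest", tr$unit_id))
  cat(sprintf("%-8s responsive pre/post %s/%s, median latency %.1f ms -> tagged: %s\n",
              tr$unit_id, r$responsive_pre, r$responsive_post,
              r$median_latency_ms, r$tagged))
}
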