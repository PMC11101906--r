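#!/usr/bin/env Rscript
# Generate the synthetic study: one session per condition preset, written
# as session directories under results/sessions/. These stand in for the
# in-vivo recordings, which are not publicly deposited; every downstream
# driver consumes only these directories.

library(spikesync)

seed <- 20260928
out_root <- "results/sessions"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

presets <- c("sham_like", "sni_like", "pv_silenced_like", "psi_ko_like")
for (preset in presets) {
  res <- preset_condition(preset, seed = seed, n_units = 16,
                          trials_per_force = 12)
  dir_out <- file.path(out_root, preset)
  save_session(res$session, dir_out)
  n_spk <- sum(vapply(res$session$trains, function(tr)
    length(tr$spike_times), 0))
  cat(sprintf("%-18s %2d units, %5d spikes, %d events -> %s\n", preset,
              length(res$session$trains), n_spk,
              nrow(res$session$events), dir_out))
}

cat("\nGround truth (per condition, mean over units):\n")
for (preset in presets) {
  gt <- jsonlite::read_json(file.path(out_root, preset, "ground_truth.json"),
                            simplifyVector = TRUE)
  cat(sprintf("%-18s p_event %.2f  theta %4.1f mN  baseline %.1f Hz\n",
              preset, mean(gt$p_event), mean(gt$theta_mN), mean(gt$b_hz)))
}
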