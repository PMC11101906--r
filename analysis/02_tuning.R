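#!/usr/bin/env Rscript
# Tuning analysis of the simulated sessions: windowed evoked rates per
# force, bootstrap response thresholds, and how well thresholds recover
# the generator's ground truth.

library(spikesync)

seed <- 41
sessions_dir <- "results/sessions"
stopifnot(dir.exists(sessions_dir))
dir.create("results", showWarnings = FALSE)

all_rows <- list()
for (preset in list.dirs(sessions_dir, recursive = FALSE)) {
  s <- load_session(preset)
  ind <- s$events[s$events$kind == "indentation", ]
  gt <- s$ground_truth
  for (i in seq_along(s$trains)) {
    uid <- names(s$trains)[i]
    th <- detect_threshold(s$trains[[i]], ind, n_boot = 1000,
                           seed = stream_seed(seed, s$condition, uid))
    all_rows[[paste(s$condition, uid)]] <- data.frame(
      condition = s$condition, unit_id = uid,
      threshold_mN = if (is.null(th$threshold_mN)) NA_real_ else th$threshold_mN,
      true_theta_mN = gt$theta_mN[match(uid, gt$unit_id)])
  }
}
tab <- do.call(rbind, all_rows)
save_results(tab, "results/thresholds.csv", config = list(n_boot = 1000),
             seed = seed)

hit <- with(tab[!is.na(tab$threshold_mN), ], threshold_mN == true_theta_mN)
cat(sprintf("Units with a threshold: %d / %d\n",
            sum(!is.na(tab$threshold_mN)), nrow(tab)))
cat(sprintf("Detected threshold equals injected threshold: %.0f%%\n",
            100 * mean(hit)))
for (cond in unique(tab$condition)) {
  sub <- tab[tab$condition == cond, ]
  cat(sprintf("%-18s mean threshold %4.1f mN (true %4.1f mN)\n", cond,
              mean(sub$threshold_mN, na.rm = TRUE), mean(sub$true_theta_mN)))
}
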