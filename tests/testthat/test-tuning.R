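# PSTHs, window rates, bootstrap thresholds, brush maxima.

# deterministic train: one spike at onset + offset_s in each trial
det_train <- function(onsets, at_s, t_stop) {
  spike_train("det", sort(onsets + at_s), t_stop)
}

test_that("PSTH counts deterministic spikes into the right bin", {
  onsets <- seq(2, 20, by = 2)
  tr <- det_train(onsets, 0.005, 25)
  p <- compute_psth(tr, onsets, bin_ms = 10)
  post <- which(p$bin_edges_s[-length(p$bin_edges_s)] >= 0)
  expect_equal(p$rate_hz[post[1]], 100)          # 1 spike / (10 trials * 10 ms)
  expect_equal(sum(p$rate_hz[-post[1]]), 0)
  expect_equal(p$baseline_hz, 0)
})

test_that("stationary Poisson PSTH is flat and centers at zero after baseline subtraction", {
  tr <- make_poisson_train(10, 620, seed = 14)
  onsets <- seq(5, 610, by = 3)
  p <- compute_psth(tr, onsets, variant = "baseline_subtracted")
  nb <- length(p$rate_hz)
  se <- sd(p$rate_hz) / sqrt(nb)
  expect_lt(abs(mean(p$rate_hz)), 2 * se + 0.05)
  praw <- compute_psth(tr, onsets)
  se_bin <- sqrt(10 / (length(onsets) * 0.01))
  expect_true(all(abs(praw$rate_hz - 10) < 4 * se_bin))
})

test_that("evoked PSTH peak matches the analytic kernel bin average", {
  # unit with A_on = 40 Hz alpha kernel (tau = 10 ms) over 3 Hz baseline
  out <- simulate_session(
    protocol_spec(forces_mN = 75, trials_per_force = 200),
    population_spec(n_units = 1, b_hz = 3, theta_mN = 75, A_on = 40,
                    A_sus = 0, A_off = 0), seed = 6)
  s <- out$session
  ind <- s$events[s$events$kind == "indentation", ]
  p <- compute_psth(s$trains[[1]], ind$onset_s, bin_ms = 10)
  # analytic bin averages of b + A * (t/tau) exp(1 - t/tau) over 10 ms bins
  alpha_int <- function(lo, hi) stats::integrate(function(t)
    (t / 0.01) * exp(1 - t / 0.01), lo, hi)$value
  bins <- seq(0, 0.04, by = 0.01)
  analytic <- 3 + 40 * vapply(seq_along(bins), function(k)
    alpha_int(bins[k], bins[k] + 0.01), 0) / 0.01
  on_bins <- which(p$bin_edges_s[-length(p$bin_edges_s)] >= 0)[1:5]
  peak_bin <- on_bins[which.max(p$rate_hz[on_bins])]
  expect_equal(p$rate_hz[peak_bin], max(analytic),
               tolerance = 0.2)
  # peak lies inside the ON window
  expect_lte(p$bin_edges_s[peak_bin], 0.05)
})

test_that("window rates follow the stated window arithmetic", {
  onsets <- c(10, 20, 30)
  trials <- data.frame(onset_s = onsets, offset_s = onsets + 0.5)
  # one spike at onset + 400 ms -> sustained only, 1 spike / 0.2 s = 5 Hz
  tr <- det_train(onsets, 0.4, 40)
  wr <- window_rates(tr, trials)
  expect_equal(unname(attr(wr, "means")["sustained_hz"]), 5)
  expect_equal(unname(attr(wr, "means")["on_hz"]), 0)
  expect_equal(unname(attr(wr, "means")["off_hz"]), 0)
  # spikes only after offset -> OFF only
  tr2 <- det_train(onsets, 0.52, 40)
  wr2 <- window_rates(tr2, trials)
  expect_gt(unname(attr(wr2, "means")["off_hz"]), 0)
  expect_equal(unname(attr(wr2, "means")["on_hz"]), 0)
  expect_equal(unname(attr(wr2, "means")["sustained_hz"]), 0)
  expect_error(window_rates(tr, data.frame(onset_s = 1, offset_s = 1.2)),
               "250 ms")
})

test_that("sustained amplitude is recovered from simulation", {
  out <- simulate_session(
    protocol_spec(forces_mN = 75, trials_per_force = 100),
    population_spec(n_units = 1, b_hz = 5, theta_mN = 75, A_on = 0,
                    A_sus = 20, A_off = 0), seed = 16)
  s <- out$session
  ind <- s$events[s$events$kind == "indentation", ]
  wr <- window_rates(s$trains[[1]], ind)
  m <- attr(wr, "means")
  se <- sd(wr$sustained_hz) / sqrt(nrow(wr))
  expect_lt(abs((m[["sustained_hz"]] - m[["baseline_hz"]]) - 20), 2 * se + 1)
})

test_that("threshold detection needs a seed and enough trials", {
  out <- simulate_session(protocol_spec(forces_mN = c(10, 75),
                                        trials_per_force = 4),
                          population_spec(n_units = 1), seed = 2)
  ind <- out$session$events
  expect_error(detect_threshold(out$session$trains[[1]], ind, seed = 1),
               "10 trials")
  out2 <- simulate_session(protocol_spec(forces_mN = c(10, 75),
                                         trials_per_force = 12),
                           population_spec(n_units = 1), seed = 2)
  expect_error(detect_threshold(out2$session$trains[[1]], out2$session$events),
               "seed")
})

test_that("a deterministic responder at the top force gets that threshold", {
  P <- protocol_spec(trials_per_force = 12)
  n_tr <- length(P$forces_mN) * P$trials_per_force
  slot <- P$baseline_s + P$step_dur_s + P$post_s
  onsets <- (seq_len(n_tr) - 1) * slot + P$baseline_s
  forces <- rep(P$forces_mN, P$trials_per_force)
  ev <- data.frame(kind = "indentation", onset_s = onsets,
                   offset_s = onsets + 0.5, force_mN = forces,
                   trial_index = seq_len(n_tr))
  # silent at baseline, 3 spikes in the ON window only at 75 mN
  times <- sort(c(outer(onsets[forces == 75], c(0.005, 0.015, 0.03), `+`)))
  tr <- spike_train("resp", times, max(onsets) + 2)
  th <- detect_threshold(tr, ev, n_boot = 200, seed = 8)
  expect_equal(th$threshold_mN, 75)
})

test_that("threshold recovery is monotone in ON amplitude", {
  P <- protocol_spec(trials_per_force = 20)
  recover <- function(A_on, seed) {
    out <- simulate_session(P, population_spec(
      n_units = 10, b_hz = 3, theta_mN = 10, A_on = A_on, A_sus = 0,
      A_off = 0, rho = 1, tuning_weights = matrix(1, 10, 6)), seed = seed)
    hits <- vapply(seq_len(10), function(i) {
      th <- detect_threshold(out$session$trains[[i]], out$session$events,
                             n_boot = 300, seed = seed + i)
      identical(th$threshold_mN, 10)
    }, TRUE)
    mean(hits)
  }
  r_strong <- recover(30, seed = 41)
  r_weak <- recover(10, seed = 41)
  expect_gte(r_strong, r_weak)
  expect_gte(r_strong, 0.8)
})

test_that("brush maxima: burst arithmetic, Poisson bound, and exclusion", {
  # 1 s burst at 100 Hz in minute 2 of 3, else silent
  burst <- 60 + 30 + 0.005 + seq(0, 0.99, by = 0.01)
  tr <- spike_train("burst", burst, 181)
  r <- brush_max_rates(tr, 0, 180)
  expect_equal(r$minute_max_hz, c(0, 100, 0))
  expect_equal(r$mean_max_hz, 100 / 3, tolerance = 1e-9)

  # constant 20 Hz: per-minute maxima below the Poisson extreme-bin bound:
  # the smallest count k whose expected exceedance over 600 bins of
  # Poisson(2) is below 0.01
  tp <- make_poisson_train(20, 180, seed = 77)
  rp <- brush_max_rates(tp, 0, 180)
  k_star <- which(600 * (1 - ppois(0:50, 2)) <= 0.01)[1] - 1
  expect_true(all(rp$minute_max_hz <= k_star / 0.1))

  # silent unit excluded by the baseline bootstrap bound
  silent <- spike_train("quiet", numeric(), 181)
  rs <- brush_max_rates(silent, 0, 180, baseline_rates_hz = rpois(40, 8) / 1.5,
                        seed = 5)
  expect_false(rs$included)
  expect_match(rs$reason, "no response above baseline")
  expect_error(brush_max_rates(tr, 0, 50), "1 min")
})
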