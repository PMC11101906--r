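# Synthetic generator: determinism, Poisson statistics, preset contrasts,
# waveform and LFP generation.

test_that("identical seeds give byte-identical sessions; seeds are mandatory", {
  P <- protocol_spec(forces_mN = c(10, 75), trials_per_force = 2)
  pop <- population_spec(n_units = 3, p_event = 0.3, event_rate_hz = 5,
                         gain_cv = 0.2, latency_mu_ms = 10)
  a <- simulate_session(P, pop, seed = 5)
  b <- simulate_session(P, pop, seed = 5)
  expect_identical(lapply(a$session$trains, `[[`, "spike_times"),
                   lapply(b$session$trains, `[[`, "spike_times"))
  expect_error(simulate_session(P, pop), "seed")
})

test_that("enlarging the population leaves existing units' spikes unchanged", {
  P <- protocol_spec(forces_mN = c(10, 75), trials_per_force = 2)
  small <- simulate_session(P, population_spec(n_units = 3, p_event = 0.2,
                                               event_rate_hz = 5), seed = 9)
  big <- simulate_session(P, population_spec(n_units = 6, p_event = 0.2,
                                             event_rate_hz = 5), seed = 9)
  for (uid in names(small$session$trains)) {
    expect_identical(big$session$trains[[uid]]$spike_times,
                     small$session$trains[[uid]]$spike_times)
  }
})

test_that("spontaneous spike counts match the Poisson mean/variance oracle", {
  # b = 10 Hz over 100 s: count within 3 * sqrt(1000) of 1000
  out <- simulate_session(protocol_spec(forces_mN = numeric(),
                                        trials_per_force = 0,
                                        spont_dur_s = 100),
                          population_spec(n_units = 4, b_hz = 10), seed = 21)
  counts <- vapply(out$session$trains, function(tr)
    sum(tr$spike_times <= 100), 0)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
})

test_that("with no shared structure, pairwise correlations vanish", {
  out <- simulate_session(
    protocol_spec(forces_mN = c(10, 75), trials_per_force = 12),
    population_spec(n_units = 8, b_hz = 10, theta_mN = 10, p_event = 0,
                    gain_cv = 0, rho = 0),
    seed = 33)
  s <- out$session
  nr <- noise_correlations(s)$noise_r
  expect_lt(abs(mean(nr)), 2 * sd(nr) / sqrt(length(nr)) + 0.02)
  sy <- pairwise_synchrony(s, epoch = "evoked", max_lag_ms = 0)$sync_r
  expect_lt(abs(mean(sy, na.rm = TRUE)), 0.02)
})

test_that("presets encode the documented parameter contrasts", {
  tiny <- protocol_spec(trials_per_force = 2)
  sham <- preset_condition("sham_like", seed = 4, n_units = 8, protocol = tiny)
  sni <- preset_condition("sni_like", seed = 4, n_units = 8, protocol = tiny)
  psi <- preset_condition("psi_ko_like", seed = 4, n_units = 8, protocol = tiny)

  sup <- sham$ground_truth$depth_um < 240
  expect_equal(mean(sni$ground_truth$p_event[sup]) /
                 mean(sham$ground_truth$p_event[sup]), 0.5)
  expect_equal(sni$ground_truth$p_event[!sup], sham$ground_truth$p_event[!sup])

  forces <- tiny$forces_mN
  idx_sham <- match(sham$ground_truth$theta_mN, forces)
  idx_psi <- match(psi$ground_truth$theta_mN, forces)
  expect_true(all(idx_psi == pmax(1L, idx_sham - 1L)))

  expect_error(preset_condition("nope", seed = 1), "sham_like")
})

test_that("pv_silenced_like raises baseline firing 1.3x in expectation", {
  # Monte-Carlo over seeds: realized spontaneous rate in trial baselines
  tiny <- protocol_spec(forces_mN = c(45, 75), trials_per_force = 2)
  rate_of <- function(name, seed) {
    s <- preset_condition(name, seed, n_units = 6, protocol = tiny)$session
    w <- epoch_windows(s, "spontaneous")
    tot <- sum(w[, 2] - w[, 1])
    mean(vapply(s$trains, function(tr)
      sum(tr$spike_times >= min(w) & tr$spike_times < max(w)) / tot, 0))
  }
  seeds <- 101:120
  r_sham <- vapply(seeds, function(sd) rate_of("sham_like", sd), 0)
  r_pv <- vapply(seeds, function(sd) rate_of("pv_silenced_like", sd), 0)
  expect_equal(mean(r_pv) / mean(r_sham), 1.3, tolerance = 0.08)
})

test_that("waveform generator hits template durations exactly at zero noise", {
  classes <- list(list(trough_to_peak_ms = 0.3), list(trough_to_peak_ms = 0.8))
  wf0 <- simulate_waveforms(5, classes, noise_sd = 0, seed = 2)
  feats <- waveform_feature_table(wf0$waveforms, wf0$fs_hz)
  expect_equal(feats$trough_to_peak_ms[wf0$labels == 0], rep(0.3, 5))
  expect_equal(feats$trough_to_peak_ms[wf0$labels == 1], rep(0.8, 5))

  # with noise, class means of duration stay within 0.05 ms of the template
  wfn <- simulate_waveforms(60, classes, noise_sd = 0.05, seed = 3)
  fn <- waveform_feature_table(wfn$waveforms, wfn$fs_hz)
  expect_lt(abs(mean(fn$trough_to_peak_ms[wfn$labels == 0], na.rm = TRUE) - 0.3), 0.05)
  expect_lt(abs(mean(fn$trough_to_peak_ms[wfn$labels == 1], na.rm = TRUE) - 0.8), 0.05)

  single <- simulate_waveforms(4, classes[1], noise_sd = 0, seed = 4)
  expect_equal(unique(single$labels), 0L)
  expect_error(simulate_waveforms(4, classes, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("LFP generator is seeded and spectrally calibrated", {
  x1 <- simulate_lfp(12, 1000, seed = 7)
  x2 <- simulate_lfp(12, 1000, seed = 7)
  expect_identical(x1, x2)
  expect_error(simulate_lfp(12, 1000, gamma_hz = 600, seed = 1), "gamma_hz")

  # pure 1/f: relative gamma equals the analytic band-integral ratio.
  # S(f) ~ 1/max(f, 1) so the ratio is log(80/30) / (1 + log(250)).
  x <- simulate_lfp(120, 1000, one_over_f_amp = 1, seed = 8)
  rel <- lfp_spectrum(x, 1000)$relative_band_power
  analytic <- log(80 / 30) / (1 + log(250))
  expect_lt(abs(rel - analytic), 0.1 * analytic + 0.005)

  # pure in-band sinusoid: essentially all power in the gamma band
  g <- simulate_lfp(20, 1000, one_over_f_amp = 0, gamma_hz = 50,
                    gamma_amp = 1, seed = 9)
  expect_gte(lfp_spectrum(g, 1000)$relative_band_power, 0.95)
})
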