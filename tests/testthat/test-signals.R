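# LFP spectra, waveform features and clustering, opto-tagging.

test_that("relative band power behaves on known spectra", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)[-1]
  pure <- sin(2 * pi * 50 * tt)
  expect_gte(lfp_spectrum(pure, fs)$relative_band_power, 0.95)

  two <- sin(2 * pi * 50 * tt) + sin(2 * pi * 150 * tt)
  expect_equal(lfp_spectrum(two, fs)$relative_band_power, 0.5,
               tolerance = 0.1)

  wn <- withr::with_seed(2, rnorm(length(tt)))
  expect_equal(lfp_spectrum(wn, fs)$relative_band_power, 0.2,
               tolerance = 0.25)

  expect_error(lfp_spectrum(pure, fs, band = c(100, 300)), "band")
  expect_error(lfp_spectrum(pure[1:2000], fs), "10 s")
})

test_that("relative band power is scale invariant and the filter zero-phase", {
  fs <- 1000
  x <- simulate_lfp(15, fs, seed = 4)
  r1 <- lfp_spectrum(x, fs)$relative_band_power
  r2 <- lfp_spectrum(2 * x, fs)$relative_band_power
  expect_equal(r1, r2, tolerance = 1e-12)

  # group delay of a delta through the forward-backward filter is 0 +/- 1
  delta <- numeric(fs * 12); delta[6000] <- 1
  bf <- signal::butter(8, 250 / (fs / 2), type = "low")
  out <- signal::filtfilt(bf, delta)
  expect_lte(abs(which.max(out) - 6000), 1)
})

test_that("waveform features follow the template geometry", {
  fs <- 20000
  wf <- numeric(60)
  wf[20] <- -1; wf[36] <- 0.5
  f <- waveform_features(wf, fs)
  expect_equal(f$trough_to_peak_ms, 0.8)
  expect_equal(f$trough_to_peak_ratio, 2)

  # scaling doubles the slope, leaves duration and ratio unchanged
  tmpl <- simulate_waveforms(1, list(list(trough_to_peak_ms = 0.5)),
                             noise_sd = 0, seed = 1)$waveforms[1, ]
  f1 <- waveform_features(tmpl, fs)
  f2 <- waveform_features(2 * tmpl, fs)
  expect_equal(f2$trough_to_peak_ms, f1$trough_to_peak_ms)
  expect_equal(f2$trough_to_peak_ratio, f1$trough_to_peak_ratio)
  expect_equal(f2$repolarization_slope, 2 * f1$repolarization_slope)

  # monotone decay has no post-trough peak: flagged
  flagged <- waveform_features(c(-(1:10)), fs)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$trough_to_peak_ms))
})

test_that("k-means recovers well-separated feature clusters", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 3),
               matrix(rnorm(60, 5, 0.1), ncol = 3),
               matrix(rnorm(60, -5, 0.1), ncol = 3))
  })
  truth <- rep(1:3, each = 20)
  cl <- cluster_waveforms(X, k = 3, seed = 6)
  # perfect agreement up to label permutation
  tab <- table(cl$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 60)
  cl2 <- cluster_waveforms(X, k = 3, seed = 6)
  expect_identical(cl$cluster, cl2$cluster)

  same <- matrix(1, 10, 3)
  dg <- cluster_waveforms(same, k = 3, seed = 1)
  expect_true(dg$degenerate)
  expect_equal(unique(dg$cluster), 1L)
  expect_error(cluster_waveforms(X[1:2, ], k = 3, seed = 1), "fewer units")
})

test_that("opto-tag classification implements the dual-block latency rule", {
  pulses_pre <- seq(2, by = 0.25, length.out = 30)
  pulses_post <- seq(12, by = 0.25, length.out = 30)
  t_stop <- 25
  # deterministic 4 ms response in both blocks -> tagged
  tr <- spike_train("tag", sort(c(pulses_pre, pulses_post) + 0.004), t_stop)
  r <- classify_optotag(tr, pulses_pre, pulses_post, seed = 2)
  expect_true(r$tagged)
  expect_lt(r$median_latency_ms, 10)

  # 15 ms response: outside the latency criterion -> not tagged
  tr15 <- spike_train("slow", sort(c(pulses_pre, pulses_post) + 0.015), t_stop)
  r15 <- classify_optotag(tr15, pulses_pre, pulses_post, seed = 2)
  expect_false(r15$tagged)

  # responsive pre, silent post: network-driven -> not tagged
  trnet <- spike_train("net", pulses_pre + 0.004, t_stop)
  rnet <- classify_optotag(trnet, pulses_pre, pulses_post, seed = 2)
  expect_true(rnet$responsive_pre)
  expect_false(isTRUE(rnet$responsive_post))
  expect_false(rnet$tagged)

  # missing post block -> tagged is NA with a reason
  rmiss <- classify_optotag(tr, pulses_pre, NULL, seed = 2)
  expect_true(is.na(rmiss$tagged))
  expect_match(rmiss$reason, "post-blocker")

  # monotonicity: pushing the latency past 10 ms can only untag
  tr9 <- spike_train("a", sort(c(pulses_pre, pulses_post) + 0.009), t_stop)
  tr11 <- spike_train("b", sort(c(pulses_pre, pulses_post) + 0.011), t_stop)
  expect_true(classify_optotag(tr9, pulses_pre, pulses_post, seed = 3)$tagged)
  expect_false(classify_optotag(tr11, pulses_pre, pulses_post, seed = 3)$tagged)
})
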