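# Population rate, coupling with shuffled null, pairwise synchrony / CCG,
# noise and signal correlations, depth stratification.

test_that("population rate counts spikes into bins", {
  # 3 units, each one spike in bin 5 of 10 (1 ms bins over 10 ms)
  cts <- c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  s <- session_from_counts(list(cts, cts, cts))
  pr <- population_rate(s, bin_ms = 1, epoch = "spontaneous")
  expect_equal(pr$counts[1:10], c(0, 0, 0, 0, 3, 0, 0, 0, 0, 0))
  # single unit: population rate equals its own binned train
  s1 <- session_from_counts(list(c(1, 0, 2, 0, 1)))
  expect_equal(population_rate(s1, 1, "spontaneous")$counts[1:5],
               c(1, 0, 2, 0, 1))
})

test_that("lag-0 synchrony equals the brute-force Pearson on the worked instance", {
  A <- c(0, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  B <- c(0, 1, 0, 1, 0, 0, 0, 1, 0, 0)
  s <- session_from_counts(list(A, B))
  ps <- pairwise_synchrony(s, bin_ms = 1, epoch = "spontaneous",
                           max_lag_ms = 0, min_spikes = 1)
  expect_equal(ps$sync_r, brute_pearson(A, B), tolerance = 1e-12)
  expect_equal(ps$sync_r, 0.52381, tolerance = 1e-4)
})

test_that("synchrony equals brute-force Pearson on random small instances", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      nb <- sample(10:50, 1)
      A <- rpois(nb, 0.7); B <- rpois(nb, 0.7)
      if (sd(A) == 0 || sd(B) == 0) next
      s <- session_from_counts(list(A, B))
      ps <- pairwise_synchrony(s, 1, "spontaneous", max_lag_ms = 0,
                               min_spikes = 1)
      expect_equal(ps$sync_r, brute_pearson(A, B), tolerance = 1e-12)
    }
  })
})

test_that("CCG is antisymmetric under pair swap and tracks shifts", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      nb <- 40
      A <- rpois(nb, 0.8); B <- rpois(nb, 0.8)
      if (sd(A) == 0 || sd(B) == 0) next
      s <- session_from_counts(list(A, B))
      ab <- pairwise_synchrony(s, 1, "spontaneous", max_lag_ms = 5,
                               min_spikes = 1)
      ba <- pairwise_synchrony(s, 1, "spontaneous", max_lag_ms = 5,
                               min_spikes = 1,
                               pairs = matrix(c("u02", "u01"), 1))
      g1 <- attr(ab, "ccg")[[1]]; g2 <- attr(ba, "ccg")[[1]]
      expect_identical(g1$r, rev(g2$r))
    }
  })
  # B = A shifted by one bin: CCG peak at lag +/-1, chance at 0
  A <- c(1, 0, 0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 1, 1, 0, 0)
  B <- c(0, A)[1:20]
  s <- session_from_counts(list(A, B))
  ps <- pairwise_synchrony(s, 1, "spontaneous", max_lag_ms = 3, min_spikes = 1)
  g <- attr(ps, "ccg")[[1]]
  expect_equal(abs(g$lag[which.max(g$r)]), 1)
  # identical trains: sync_r = 1
  s2 <- session_from_counts(list(A, A))
  expect_equal(pairwise_synchrony(s2, 1, "spontaneous", max_lag_ms = 0,
                                  min_spikes = 1)$sync_r, 1)
})

test_that("coupling matches a hand-constructed brute-force instance", {
  # unit 1 spikes every 10 ms over 1 s; 9 others spike in the same bins
  cts <- integer(1000); cts[seq(5, 1000, by = 10)] <- 1
  s <- session_from_counts(rep(list(cts), 10))
  cp <- population_coupling(s, bin_ms = 1, epoch = "spontaneous",
                            n_shuffles = 100, seed = 3)
  # brute force: for each of unit 1's spikes, 9 coincident other spikes
  own <- cts
  pop_others <- 9 * cts
  brute_stpr_hz <- sum(own * pop_others) / sum(own) / 0.001
  expect_equal(cp$stpr_lag0_hz[1], brute_stpr_hz)     # = 9000 Hz
  # shuffle median near the mean population rate (900 Hz), so coupling
  # lands near 8100 Hz
  expect_equal(cp$shuffle_median_hz[1], 900, tolerance = 0.15)
  expect_equal(cp$coupling_hz[1], 8100, tolerance = 0.05)
})

test_that("coupling is invariant to unit relabeling and ordering", {
  out <- simulate_session(protocol_spec(forces_mN = numeric(),
                                        trials_per_force = 0,
                                        spont_dur_s = 30),
                          population_spec(n_units = 6, b_hz = 10,
                                          p_event = 0.4,
                                          event_rate_spont_hz = 3),
                          seed = 12)
  s <- out$session
  cp1 <- population_coupling(s, epoch = "spontaneous", seed = 7)
  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- s
  s2$trains <- s$trains[perm]
  s2$meta <- s$meta[perm, ]
  cp2 <- population_coupling(s2, epoch = "spontaneous", seed = 7)
  m1 <- cp1[order(cp1$unit_id), ]
  m2 <- cp2[order(cp2$unit_id), ]
  expect_equal(m2$stpr_lag0_hz, m1$stpr_lag0_hz)
  expect_equal(m2$coupling_hz, m1$coupling_hz)
})

test_that("coupling increases monotonically with injected participation", {
  mean_coupling <- function(p) {
    out <- simulate_session(
      protocol_spec(forces_mN = numeric(), trials_per_force = 0,
                    spont_dur_s = 60),
      population_spec(n_units = 8, b_hz = 5, p_event = p,
                      event_rate_spont_hz = 4, sigma_sync_ms = 1),
      seed = 31)
    cp <- population_coupling(out$session, epoch = "spontaneous", seed = 55)
    mean(cp$coupling_hz, na.rm = TRUE)
  }
  cps <- vapply(c(0, 0.2, 0.5), mean_coupling, 0)
  expect_true(all(diff(cps) > 0))
})

test_that("units below the spike minimum are flagged, small strata skipped", {
  trains <- c(list(spike_train("sparse", c(1, 2, 3), 31)),
              lapply(1:5, function(i) make_poisson_train(10, 31, seed = i,
                                                         unit_id = paste0("u", i))))
  s <- wrap_session(trains, spont_dur_s = 30)
  cp <- population_coupling(s, epoch = "spontaneous", seed = 2)
  expect_true(is.na(cp$coupling_hz[cp$unit_id == "sparse"]))
  expect_error(population_coupling(s, epoch = "spontaneous", seed = 2,
                                   stratum = "superficial"), "at least 5")

  # all units superficial: deep stratum skipped with a warning
  s3 <- wrap_session(lapply(1:6, function(i)
    make_poisson_train(10, 31, seed = i, unit_id = paste0("u", i))),
    spont_dur_s = 30, depth_um = rep(100, 6))
  expect_warning(st <- stratify_coupling(s3, epoch = "spontaneous", seed = 4),
                 "deep")
  expect_true(all(st$stratum == "superficial"))
})

test_that("the stratum boundary is half-open at 240 um", {
  s <- wrap_session(lapply(1:2, function(i)
    make_poisson_train(5, 10, seed = i, unit_id = paste0("u", i))),
    spont_dur_s = 10, depth_um = c(239.9, 240))
  st <- unit_strata(s)
  expect_equal(unname(st), c("superficial", "deep"))
})

test_that("noise correlations: self-pair is 1, zero-variance is NA", {
  tr <- make_poisson_train(10, 130, seed = 8, unit_id = "a")
  tr2 <- spike_train("b", tr$spike_times, tr$t_stop)
  onsets <- seq(2, 128, by = 2.5)
  ev <- data.frame(kind = "indentation", onset_s = onsets,
                   offset_s = onsets + 0.5, force_mN = 10,
                   trial_index = seq_along(onsets))
  s <- wrap_session(list(tr, tr2, spike_train("silent", numeric(), 130)),
                    events = ev)
  nc <- noise_correlations(s)
  expect_equal(nc$noise_r[nc$unit_a == "a" & nc$unit_b == "b"], 1)
  expect_true(is.na(nc$noise_r[nc$unit_b == "silent"][1]))
  expect_error(noise_correlations(s, windows = cbind(1:5, 2:6)), "20")
})

test_that("signal correlation is exactly 1 for affine-related mean PSTHs", {
  # deterministic counts per 50 ms bin: y = 2 x + 1 spikes per bin
  onsets <- seq(2, 40, by = 2.5)
  x_counts <- c(1, 3, 0, 2, 1, 4, 0, 2, 3, 1)
  place <- function(counts_per_bin) {
    sort(unlist(lapply(onsets, function(on)
      unlist(lapply(seq_along(counts_per_bin), function(b) {
        k <- counts_per_bin[b]
        if (k == 0) return(numeric())
        on + (b - 1) * 0.05 + 0.05 * seq_len(k) / (k + 1)
      })))))
  }
  trA <- spike_train("A", place(x_counts), 45)
  trB <- spike_train("B", place(2 * x_counts + 1), 45)
  ev <- data.frame(kind = "indentation", onset_s = onsets,
                   offset_s = onsets + 0.5, force_mN = 10,
                   trial_index = seq_along(onsets))
  s <- wrap_session(list(trA, trB), events = ev)
  sc <- signal_correlations(s)
  expect_equal(sc$signal_r, 1, tolerance = 1e-12)
})
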