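# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Homogeneous Poisson spike train.
make_poisson_train <- function(rate_hz, t_stop, seed, unit_id = "u") {
  withr::with_seed(seed, {
    n <- stats::rpois(1, rate_hz * t_stop)
    st <- sort(stats::runif(n, 0, t_stop))
    if (length(st) > 1) st <- st[c(TRUE, diff(st) >= 50e-6)]
    spike_train(unit_id, st, t_stop)
  })
}

# Session whose units' spike times are placed at the centers of given
# 1-bin_s count vectors (counts 0/1 per bin), over a leading spontaneous
# block. Used for hand-constructed synchrony instances.
session_from_counts <- function(count_list, bin_s = 0.001) {
  nb <- length(count_list[[1]])
  t_stop <- nb * bin_s + 1
  trains <- lapply(seq_along(count_list), function(i) {
    cts <- count_list[[i]]
    times <- unlist(lapply(which(cts > 0), function(b) {
      (b - 1) * bin_s + bin_s * seq_len(cts[b]) / (cts[b] + 1)
    }))
    spike_train(sprintf("u%02d", i), sort(times), t_stop)
  })
  names(trains) <- vapply(trains, `[[`, "", "unit_id")
  meta <- data.frame(unit_id = names(trains),
                     depth_um = seq(50, 600, length.out = length(trains)),
                     channel = seq_along(trains))
  ev <- data.frame(kind = character(), onset_s = numeric(),
                   offset_s = numeric(), force_mN = numeric(),
                   block = character(), trial_index = integer())
  session("counts", trains, meta, ev, spont_dur_s = nb * bin_s)
}

# Brute-force Pearson correlation from first principles (independent of
# stats::cor), used as the synchrony oracle.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Minimal valid session around a list of spike trains (no events needed).
wrap_session <- function(trains, spont_dur_s = NULL, events = NULL,
                         depth_um = NULL) {
  names(trains) <- vapply(trains, `[[`, "", "unit_id")
  n <- length(trains)
  meta <- data.frame(unit_id = names(trains),
                     depth_um = depth_um %||% seq(50, 600, length.out = n),
                     channel = seq_len(n))
  if (is.null(events)) {
    events <- data.frame(kind = character(), onset_s = numeric(),
                         offset_s = numeric(), force_mN = numeric(),
                         block = character(), trial_index = integer())
  }
  session("wrap", trains, meta, events,
          spont_dur_s = spont_dur_s %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
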