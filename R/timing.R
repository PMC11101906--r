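# First-spike latency against a shuffled null, and jitter as the
# across-trial SD of first-spike latencies.

# Cumulative first-spike latency curve: entry k is the number of trials
# whose first spike in (0, win] falls at or before k * bin_s.
.cum_latency_curve <- function(latencies, win_s, bin_s) {
  nb <- ceiling(win_s / bin_s - 1e-9)
  lat <- latencies[!is.na(latencies)]
  if (length(lat) == 0) return(integer(nb))
  idx <- pmin(nb, ceiling(lat / bin_s - 1e-12))
  cumsum(tabulate(idx, nbins = nb))
}

# First spike in (0, win] of each row of a list of relative spike vectors.
.first_in_window <- function(rel_spikes, win_s) {
  vapply(rel_spikes, function(sp) {
    sp <- sp[sp > 0 & sp <= win_s]
    if (length(sp)) min(sp) else NA_real_
  }, 0)
}

#' Shuffled-null envelope test for stimulus-locked first spikes
#'
#' Shared machinery for [latency_and_jitter()] and [classify_optotag()].
#' Per trial, spikes within `(onset - pre_s, onset + win_s]` are collected;
#' the empirical cumulative first-spike-latency curve (in `bin_s` bins over
#' `(0, win_s]`) is compared against curves computed from trains whose
#' spike times are redrawn uniformly within the same per-trial window
#' (spike counts preserved), `n_shuffles` times.
#'
#' Two bands are available. `"global"` (default) is a rank envelope whose
#' per-bin order statistic is chosen so that the fraction of *null* curves
#' exceeding the band anywhere is at most `alpha` — a family-wise test over
#' bins. `"pointwise"` uses the per-bin 97.5th percentile, which is liberal
#' when many bins are scanned.
#'
#' @param train a `spike_train`
#' @param onsets stimulus onset times (s)
#' @param win_s search window after onset (s)
#' @param pre_s shuffle window extent before onset (s)
#' @param bin_s curve bin width (s)
#' @param n_shuffles shuffle count
#' @param alpha test level
#' @param seed integer seed
#' @param band `"global"` or `"pointwise"`
#' @return list: `latency_s` (left edge of the first crossing bin, or `NA`),
#'   `jitter_s` (SD of per-trial first-spike latencies, trials with a spike
#'   only), `latencies_s`, `n_trials`, `n_with_spike`, `curve`, `band_upper`
#' @export
first_spike_envelope <- function(train, onsets, win_s = 0.1, pre_s = 1.5,
                                 bin_s = 0.001, n_shuffles = 100,
                                 alpha = 0.05, seed,
                                 band = c("global", "pointwise")) {
  if (missing(seed) || is.null(seed)) stop("seed is required for the shuffle null")
  band <- match.arg(band)
  st <- train$spike_times
  rel <- lapply(onsets, function(on) st[st > on - pre_s & st <= on + win_s] - on)
  counts <- lengths(rel)
  lat <- .first_in_window(rel, win_s)
  curve <- .cum_latency_curve(lat, win_s, bin_s)
  nb <- length(curve)

  S <- withr::with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(s) {
      sh_lat <- vapply(seq_along(onsets), function(k) {
        if (counts[k] == 0) return(NA_real_)
        sp <- stats::runif(counts[k], -pre_s, win_s)
        sp <- sp[sp > 0]
        if (length(sp)) min(sp) else NA_real_
      }, 0)
      as.numeric(.cum_latency_curve(sh_lat, win_s, bin_s))
    }, numeric(nb)))
  })

  if (band == "pointwise") {
    upper <- apply(S, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  } else {
    # rank envelope: smallest order statistic r such that <= alpha of the
    # null curves themselves exceed the r-th-order band anywhere
    less_counts <- apply(S, 2, function(col) rank(col, ties.method = "min") - 1)
    M <- apply(less_counts, 1, max)    # per null curve: max per-bin rank
    ord <- apply(S, 2, sort)
    r_star <- NA_integer_
    for (r in seq_len(n_shuffles)) {
      if (mean(M >= r) <= alpha) { r_star <- r; break }
    }
    upper <- if (is.na(r_star)) rep(Inf, nb) else ord[r_star, ]
  }

  crossing <- which(curve > upper)
  latency_s <- if (length(crossing)) (min(crossing) - 1) * bin_s else NA_real_
  with_spike <- lat[!is.na(lat)]
  jitter_s <- if (is.na(latency_s) || length(with_spike) < 2) NA_real_ else stats::sd(with_spike)
  list(latency_s = latency_s, jitter_s = jitter_s, latencies_s = lat,
       n_trials = length(onsets), n_with_spike = length(with_spike),
       curve = curve, band_upper = upper, bin_s = bin_s)
}

#' First-spike latency and jitter for step indentation
#'
#' The distribution of first-spike latencies after stimulus onset is
#' compared to a shuffled distribution; the time at which the empirical
#' cumulative curve exceeds the 95% shuffle band is the latency, and the
#' SD of per-trial first-spike latencies is the jitter. At least 50 trials
#' are required.
#'
#' @param train a `spike_train`
#' @param onsets onset times of the trials at one force (s)
#' @param search_window_ms latency search window after onset (ms)
#' @param n_shuffles shuffle count (at least 100)
#' @param alpha test level
#' @param bin_ms curve bin width (ms)
#' @param seed integer seed (mandatory)
#' @param pre_s shuffle window extent before onset (s)
#' @param band `"global"` or `"pointwise"` (see [first_spike_envelope()])
#' @param min_trials minimum trial count, default 50
#' @return list of class `latency_result`: `latency_ms`, `jitter_ms`
#'   (both `NA` when no crossing), `n_trials`, `n_trials_with_spike`
#' @export
latency_and_jitter <- function(train, onsets, search_window_ms = 100,
                               n_shuffles = 100, alpha = 0.05, bin_ms = 1,
                               seed, pre_s = 1.5, band = "global",
                               min_trials = 50) {
  if (length(onsets) < min_trials) {
    stop("a minimum of ", min_trials, " trials is required (have ",
         length(onsets), ")")
  }
  env <- first_spike_envelope(train, onsets, win_s = search_window_ms / 1000,
                              pre_s = pre_s, bin_s = bin_ms / 1000,
                              n_shuffles = n_shuffles, alpha = alpha,
                              seed = seed, band = band)
  structure(list(latency_ms = env$latency_s * 1000,
                 jitter_ms = env$jitter_s * 1000,
                 n_trials = env$n_trials,
                 n_trials_with_spike = env$n_with_spike,
                 envelope = env),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency %.1f ms, jitter %.2f ms (%d/%d trials with spike)>\n",
              x$latency_ms, x$jitter_ms, x$n_trials_with_spike, x$n_trials))
  invisible(x)
}
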