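# Tuning: PSTHs, windowed evoked rates, bootstrap response thresholds, and
# brush response maxima.

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate in `bin_ms` bins over
#' `[-baseline_s, step_dur + 0.3]` s around stimulus onset. Baseline mean
#' and SD are computed across the baseline bins of the trial-averaged rate.
#'
#' @param train a `spike_train`
#' @param onsets indentation onset times (s) of the trials to average
#'   (typically all trials at one force)
#' @param bin_ms bin width (ms), default 10
#' @param variant `"raw"`, `"baseline_subtracted"` or `"zscored"`
#' @param baseline_s baseline span before onset (s)
#' @param step_dur_s step duration (s)
#' @param post_s span beyond offset included in the histogram (s)
#' @return object of class `psth`: `bin_edges_s` (relative to onset),
#'   `rate_hz`, `baseline_hz`, `baseline_sd_hz`, `variant`, `n_trials`
#' @export
compute_psth <- function(train, onsets, bin_ms = 10,
                         variant = c("raw", "baseline_subtracted", "zscored"),
                         baseline_s = 1.5, step_dur_s = 0.5, post_s = 0.3) {
  variant <- match.arg(variant)
  if (length(onsets) < 1) stop("compute_psth requires at least one trial")
  bin_s <- bin_ms / 1000
  span <- c(-baseline_s, step_dur_s + post_s)
  nb <- floor((span[2] - span[1]) / bin_s + 1e-9)
  edges <- span[1] + (0:nb) * bin_s
  counts <- numeric(nb)
  for (on in onsets) {
    b <- bin_over_windows(train$spike_times, cbind(on + span[1], on + span[1] + nb * bin_s),
                          bin_s)
    counts <- counts + b$counts
  }
  rate <- counts / (length(onsets) * bin_s)
  base_bins <- which(edges[-1] <= 0 + 1e-12)
  baseline_hz <- mean(rate[base_bins])
  baseline_sd <- stats::sd(rate[base_bins])
  out <- rate
  flagged <- FALSE
  if (variant == "baseline_subtracted") {
    out <- rate - baseline_hz
  } else if (variant == "zscored") {
    if (is.na(baseline_sd) || baseline_sd == 0) {
      out <- rep(NA_real_, nb)
      flagged <- TRUE
    } else {
      out <- (rate - baseline_hz) / baseline_sd
    }
  }
  structure(list(bin_edges_s = edges, rate_hz = out, raw_rate_hz = rate,
                 baseline_hz = baseline_hz, baseline_sd_hz = baseline_sd,
                 variant = variant, n_trials = length(onsets),
                 flagged_zero_sd = flagged),
            class = "psth")
}

#' Windowed evoked rates per trial
#'
#' ON = (0, 50] ms after onset; OFF = (0, 50] ms after offset;
#' SUSTAINED = the 200 ms before offset. Rates are counts divided by window
#' length; the per-trial baseline (1.5 s before onset) is returned so
#' baseline-subtracted variants are available downstream.
#'
#' @param train a `spike_train`
#' @param trials data.frame with `onset_s`, `offset_s` (one force)
#' @param baseline_s baseline length (s)
#' @return data.frame, one row per trial: `on_hz`, `off_hz`, `sustained_hz`,
#'   `baseline_hz`; trial means in `attr(, "means")`
#' @export
window_rates <- function(train, trials, baseline_s = 1.5) {
  if (any(trials$offset_s - trials$onset_s < 0.25)) {
    stop("step shorter than 250 ms: ON and sustained windows would overlap")
  }
  st <- train$spike_times
  on_hz <- off_hz <- sus_hz <- base_hz <- numeric(nrow(trials))
  for (k in seq_len(nrow(trials))) {
    on <- trials$onset_s[k]; off <- trials$offset_s[k]
    on_hz[k] <- count_in(st, on, on + .win_on_s) / .win_on_s
    off_hz[k] <- count_in(st, off, off + .win_off_s) / .win_off_s
    sus_hz[k] <- count_in(st, off - .win_sus_s, off) / .win_sus_s
    base_hz[k] <- count_in(st, on - baseline_s, on) / baseline_s
  }
  out <- data.frame(trial = seq_len(nrow(trials)), on_hz = on_hz,
                    off_hz = off_hz, sustained_hz = sus_hz,
                    baseline_hz = base_hz)
  attr(out, "means") <- c(on_hz = mean(on_hz), off_hz = mean(off_hz),
                          sustained_hz = mean(sus_hz),
                          baseline_hz = mean(base_hz))
  out
}

# Baseline spike rates chopped into segments of length win_s, pooled over
# all trials. Used to build the bootstrap null for window statistics.
.baseline_segments <- function(st, onsets, baseline_s, win_s) {
  nseg <- floor(baseline_s / win_s + 1e-9)
  rates <- numeric(0)
  for (on in onsets) {
    b <- bin_over_windows(st, cbind(on - baseline_s, on - baseline_s + nseg * win_s),
                          win_s)
    rates <- c(rates, b$counts / win_s)
  }
  rates
}

#' Bootstrap response-threshold detection
#'
#' The threshold is the smallest force whose trial-mean rate in any of the
#' ON, OFF or sustained windows exceeds a bootstrap bound derived from the
#' unit's own pre-stimulus baseline firing; units whose firing never
#' exceeds the bound have no threshold (`NULL`, excluded downstream).
#'
#' Two bootstrap schemes are provided. The default, `"max_null"`, resamples
#' the baseline in segments matching each response window's length and takes
#' the `(1 - alpha)` quantile of the maximum window statistic across all
#' (force, window) combinations, so the probability that a purely
#' spontaneous unit is assigned any threshold is `alpha` by construction.
#' `"naive"` bootstraps the mean of the per-trial baseline rates and uses
#' its 97.5th percentile as the bound for every comparison; because the
#' baseline mean is far less variable than a 50 ms window statistic this
#' bound is anti-conservative, and the scheme is retained only for
#' comparison.
#'
#' @param train a `spike_train`
#' @param events indentation event table over all forces (`onset_s`,
#'   `offset_s`, `force_mN`)
#' @param n_boot bootstrap iterations, default 1000
#' @param alpha detection level, default 0.05
#' @param seed integer seed (mandatory)
#' @param method `"max_null"` (default) or `"naive"`
#' @param baseline_s baseline length (s)
#' @param min_trials minimum trials per force
#' @return list: `threshold_mN` (or `NULL`), `bound_hz`, `table`
#'   (per force x window trial-mean rates and exceedance flags)
#' @export
detect_threshold <- function(train, events, n_boot = 1000, alpha = 0.05, seed,
                             method = c("max_null", "naive"),
                             baseline_s = 1.5, min_trials = 10) {
  if (missing(seed) || is.null(seed)) stop("seed is required for the bootstrap")
  method <- match.arg(method)
  ind <- events
  if ("kind" %in% names(ind)) ind <- ind[ind$kind == "indentation", , drop = FALSE]
  ind <- ind[!is.na(ind$force_mN), , drop = FALSE]
  forces <- sort(unique(ind$force_mN))
  n_per <- table(ind$force_mN)
  if (any(n_per < min_trials)) {
    stop("need at least ", min_trials, " trials per force")
  }
  st <- train$spike_times
  if (any(ind$onset_s - baseline_s < 0)) stop("missing baselines before first trial")

  win_len <- c(on = .win_on_s, off = .win_off_s, sustained = .win_sus_s)
  # observed trial-mean window rates per force
  obs <- matrix(NA_real_, length(forces), 3,
                dimnames = list(forces, names(win_len)))
  for (fi in seq_along(forces)) {
    tr <- ind[ind$force_mN == forces[fi], , drop = FALSE]
    wr <- window_rates(train, tr, baseline_s = baseline_s)
    obs[fi, ] <- attr(wr, "means")[c("on_hz", "off_hz", "sustained_hz")]
  }

  n_trials_f <- as.integer(n_per[as.character(forces)])
  withr::with_seed(seed, {
    if (method == "max_null") {
      segs <- lapply(win_len, function(w) .baseline_segments(st, ind$onset_s, baseline_s, w))
      maxstat <- rep(-Inf, n_boot)
      for (wi in seq_along(win_len)) {
        pool <- segs[[wi]]
        for (fi in seq_along(forces)) {
          draws <- matrix(pool[sample.int(length(pool), n_boot * n_trials_f[fi],
                                          replace = TRUE)], nrow = n_boot)
          maxstat <- pmax(maxstat, rowMeans(draws))
        }
      }
      bound <- stats::quantile(maxstat, 1 - alpha, names = FALSE)
    } else {
      base_rates <- vapply(ind$onset_s, function(on)
        count_in(st, on - baseline_s, on) / baseline_s, 0)
      boots <- vapply(seq_len(n_boot), function(b)
        mean(base_rates[sample.int(length(base_rates), replace = TRUE)]), 0)
      bound <- stats::quantile(boots, 1 - alpha / 2, names = FALSE)
    }
  })

  exceeds <- obs > bound
  hit <- which(rowSums(exceeds) > 0)
  threshold <- if (length(hit)) forces[min(hit)] else NULL
  tab <- data.frame(force_mN = rep(forces, 3),
                    window = rep(names(win_len), each = length(forces)),
                    rate_hz = as.vector(obs), exceeds = as.vector(exceeds))
  list(threshold_mN = threshold, bound_hz = bound, table = tab,
       method = method)
}

#' Brush response maxima
#'
#' For a unit responding above baseline during the brush epoch, the firing
#' rate is smoothed into `smooth_bin_ms` bins; the maximum of the smoothed
#' trace is taken per whole minute and the per-minute maxima averaged.
#' Inclusion uses the same bootstrap logic as [detect_threshold()]: the
#' brush-epoch mean rate must exceed the 97.5th percentile of bootstrap
#' means of the per-trial baseline rates.
#'
#' @param train a `spike_train`
#' @param brush_onset_s,brush_offset_s brush epoch bounds (s); at least one
#'   minute long
#' @param baseline_rates_hz per-trial baseline rates for the inclusion test;
#'   `NULL` skips the test
#' @param smooth_bin_ms smoothing bin (ms), default 100
#' @param n_boot,seed bootstrap settings for the inclusion test
#' @return list: `included`, `reason`, `minute_max_hz`, `mean_max_hz`
#' @export
brush_max_rates <- function(train, brush_onset_s, brush_offset_s,
                            baseline_rates_hz = NULL, smooth_bin_ms = 100,
                            n_boot = 1000, seed = 1) {
  dur <- brush_offset_s - brush_onset_s
  if (dur < 60) stop("brush epoch shorter than 1 min")
  st <- train$spike_times
  if (!is.null(baseline_rates_hz)) {
    brush_rate <- count_in(st, brush_onset_s, brush_offset_s) / dur
    bound <- withr::with_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(b)
        mean(baseline_rates_hz[sample.int(length(baseline_rates_hz), replace = TRUE)]), 0)
      stats::quantile(boots, 0.975, names = FALSE)
    })
    if (!(brush_rate > bound)) {
      return(list(included = FALSE, reason = "no response above baseline",
                  minute_max_hz = NULL, mean_max_hz = NULL))
    }
  }
  n_min <- floor(dur / 60)
  bin_s <- smooth_bin_ms / 1000
  minute_max <- vapply(seq_len(n_min), function(m) {
    lo <- brush_onset_s + (m - 1) * 60
    b <- bin_over_windows(st, cbind(lo, lo + 60), bin_s)
    max(b$counts / bin_s)
  }, 0)
  list(included = TRUE, reason = NULL, minute_max_hz = minute_max,
       mean_max_hz = mean(minute_max))
}
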