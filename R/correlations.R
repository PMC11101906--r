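# Firing correlations: population rate and coupling with a shuffled-spike
# null, pairwise lag-0 synchrony and cross-correlograms, noise and signal
# correlations, and depth stratification.

#' Summed population rate
#'
#' Sums simultaneously recorded single-unit activity into a population count
#' vector at `bin_ms` resolution over the windows of the chosen epoch.
#'
#' @param session a `session` with at least 2 units (1 allowed, trivially)
#' @param bin_ms bin width (ms), default 1
#' @param epoch epoch label passed to [epoch_windows()]
#' @param per_unit divide by the number of units
#' @return list: `counts` (or Hz if converted), `bin_s`, `segment`,
#'   `n_units`
#' @export
population_rate <- function(session, bin_ms = 1, epoch = "evoked",
                            per_unit = FALSE) {
  windows <- epoch_windows(session, epoch)
  b <- bin_session(session, windows, bin_ms / 1000)
  counts <- colSums(b$counts)
  if (per_unit) counts <- counts / nrow(b$counts)
  list(counts = counts, bin_s = b$bin_s, segment = b$segment,
       n_units = nrow(b$counts))
}

#' Population coupling via the spike-triggered population rate
#'
#' For each unit, the spike-triggered population rate at zero lag is the
#' mean count of all *other* units' spikes falling in the same `bin_ms` bin
#' as each of the unit's spikes, converted to Hz. The null redraws the
#' trigger unit's spike times uniformly over the analysis epoch (the rest of
#' the population held fixed) `n_shuffles` times; the reported coupling is
#' the observed value minus the median of the null — the "normalized
#' population firing rate". Units contributing fewer than 10 spikes to the
#' epoch are returned with `NA` coupling and flagged.
#'
#' @param session a `session`
#' @param bin_ms bin width (ms); 1, 3 and 10 are the conventional choices
#' @param epoch epoch label (see [epoch_windows()])
#' @param n_shuffles shuffle count, default 100
#' @param stratum `"all"`, `"superficial"` or `"deep"`; stratification
#'   restricts both the trigger units and the population
#' @param boundary_um depth boundary for stratification (superficial is
#'   `[0, boundary)`)
#' @param seed integer seed (mandatory)
#' @param shuffle_all also redraw the rest of the population in the null
#'   (alternative scheme; default shuffles only the trigger unit)
#' @param min_spikes minimum trigger spikes in epoch
#' @param min_units minimum simultaneous units required
#' @return data.frame, one row per unit: `unit_id`, `n_spikes`,
#'   `stpr_lag0_hz`, `shuffle_median_hz`, `coupling_hz`, `bin_ms`,
#'   `stratum`, `epoch`
#' @export
population_coupling <- function(session, bin_ms = 1, epoch = "evoked",
                                n_shuffles = 100, stratum = "all",
                                boundary_um = 240, seed,
                                shuffle_all = FALSE, min_spikes = 10,
                                min_units = 5) {
  if (missing(seed) || is.null(seed)) stop("seed is required for the shuffle null")
  stratum <- match.arg(stratum, c("all", "superficial", "deep"))
  ids <- session$meta$unit_id
  if (stratum != "all") {
    ids <- ids[unit_strata(session, boundary_um) == stratum]
  }
  if (length(ids) < min_units) {
    stop("need at least ", min_units, " simultaneous units in stratum '",
         stratum, "' (have ", length(ids), ")")
  }
  windows <- epoch_windows(session, epoch)
  bin_s <- bin_ms / 1000
  b <- bin_session(session, windows, bin_s, unit_ids = ids)
  C <- b$counts
  B <- ncol(C)
  pop <- colSums(C)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    own <- C[i, ]
    popm <- pop - own                      # population excluding the trigger
    N <- sum(own)
    if (N < min_spikes) {
      out[[i]] <- data.frame(unit_id = ids[i], n_spikes = N,
                             stpr_lag0_hz = NA_real_, shuffle_median_hz = NA_real_,
                             coupling_hz = NA_real_)
      next
    }
    obs_hz <- sum(own * popm) / N / bin_s
    sh <- withr::with_seed(stream_seed(seed, "coupling", ids[i]), {
      ref <- popm
      vapply(seq_len(n_shuffles), function(s) {
        if (shuffle_all) {
          ref <- Reduce(`+`, lapply(seq_along(ids)[-i], function(j) {
            tabulate(sample.int(B, sum(C[j, ]), replace = TRUE), nbins = B)
          }))
        }
        mean(ref[sample.int(B, N, replace = TRUE)])
      }, 0)
    })
    shuffle_med_hz <- stats::median(sh) / bin_s
    out[[i]] <- data.frame(unit_id = ids[i], n_spikes = N,
                           stpr_lag0_hz = obs_hz,
                           shuffle_median_hz = shuffle_med_hz,
                           coupling_hz = obs_hz - shuffle_med_hz)
  }
  res <- do.call(rbind, out)
  res$bin_ms <- bin_ms
  res$stratum <- stratum
  res$epoch <- epoch
  res
}

#' Population coupling across bin sizes
#'
#' Runs [population_coupling()] at each requested bin size (default the
#' 1, 3, 10 ms sweep used to constrain the timescale of synchrony).
#'
#' @inheritParams population_coupling
#' @param bins_ms bin sizes to sweep
#' @return row-bound coupling tables with a `bin_ms` column
#' @export
coupling_bin_sweep <- function(session, bins_ms = c(1, 3, 10), epoch = "evoked",
                               n_shuffles = 100, stratum = "all",
                               boundary_um = 240, seed, ...) {
  do.call(rbind, lapply(bins_ms, function(bm) {
    population_coupling(session, bin_ms = bm, epoch = epoch,
                        n_shuffles = n_shuffles, stratum = stratum,
                        boundary_um = boundary_um,
                        seed = stream_seed(seed, "sweep", round(bm * 1000)), ...)
  }))
}

# Pearson correlation of two binned count vectors at each lag, never letting
# a lag straddle a segment boundary. Returns NA where a count vector has
# zero variance.
.ccg_pair <- function(x, y, segment, max_lag) {
  lags <- -max_lag:max_lag
  segs <- split(seq_along(x), segment)
  r <- vapply(lags, function(l) {
    xs <- ys <- numeric(0)
    for (idx in segs) {
      n <- length(idx)
      if (n <= abs(l)) next
      if (l >= 0) {
        xs <- c(xs, x[idx[1:(n - l)]]); ys <- c(ys, y[idx[(1 + l):n]])
      } else {
        xs <- c(xs, x[idx[(1 - l):n]]); ys <- c(ys, y[idx[1:(n + l)]])
      }
    }
    if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, 0)
  data.frame(lag = lags, r = r)
}

#' Pairwise synchrony at zero lag and cross-correlograms
#'
#' Both trains are binned at `bin_ms` over the epoch; `sync_r` is the
#' Pearson correlation of the two count vectors at zero lag, and the CCG is
#' the same correlation at each lag within `max_lag_ms`. Lags never straddle
#' the boundary between epoch windows. Pairs in which either unit has fewer
#' than `min_spikes` spikes in the epoch, or a zero-variance count vector,
#' are returned with `NA` and a reason.
#'
#' @param session a `session`
#' @param bin_ms bin width (ms), default 1
#' @param epoch epoch label
#' @param max_lag_ms CCG half-width (ms); 0 skips the CCG
#' @param min_spikes per-unit minimum spikes in epoch
#' @param pairs optional 2-column matrix of unit ids to restrict to
#' @return data.frame, one row per pair: `unit_a`, `unit_b`, `sync_r`,
#'   `n_bins`, `epoch`, `reason`; CCGs in `attr(, "ccg")` (named list of
#'   data.frames)
#' @export
pairwise_synchrony <- function(session, bin_ms = 1, epoch = "evoked",
                               max_lag_ms = 50, min_spikes = 10,
                               pairs = NULL) {
  windows <- epoch_windows(session, epoch)
  bin_s <- bin_ms / 1000
  b <- bin_session(session, windows, bin_s)
  C <- b$counts
  ids <- rownames(C)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  max_lag <- round(max_lag_ms / bin_ms)
  rows <- vector("list", nrow(pairs))
  ccgs <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; bb <- pairs[k, 2]
    x <- C[a, ]; y <- C[bb, ]
    reason <- NA_character_
    sync_r <- NA_real_
    if (sum(x) < min_spikes || sum(y) < min_spikes) {
      reason <- "fewer than min_spikes in epoch"
    } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason <- "zero-variance count vector"
    } else {
      sync_r <- stats::cor(x, y)
      if (max_lag > 0) {
        ccgs[[paste(a, bb, sep = ":")]] <- .ccg_pair(x, y, b$segment, max_lag)
      }
    }
    rows[[k]] <- data.frame(unit_a = a, unit_b = bb, sync_r = sync_r,
                            n_bins = ncol(C), epoch = epoch, reason = reason)
  }
  out <- do.call(rbind, rows)
  out$bin_ms <- bin_ms
  attr(out, "ccg") <- ccgs
  out
}

#' Trial-by-trial noise correlations
#'
#' Spike counts per unit in matched windows (by default the per-trial 1.5 s
#' pre-stimulus baselines) are correlated across windows for every pair.
#'
#' @param session a `session`
#' @param windows two-column matrix of count windows; default the per-trial
#'   baselines
#' @param baseline_s baseline length used for the default windows
#' @param min_windows minimum number of windows, default 20
#' @return data.frame per pair: `unit_a`, `unit_b`, `noise_r`, `n_windows`
#' @export
noise_correlations <- function(session, windows = NULL, baseline_s = 1.5,
                               min_windows = 20) {
  if (is.null(windows)) {
    ind <- session$events[session$events$kind == "indentation", , drop = FALSE]
    windows <- cbind(ind$onset_s - baseline_s, ind$onset_s)
  }
  windows <- as.matrix(windows)
  if (nrow(windows) < min_windows) {
    stop("need at least ", min_windows, " count windows (have ", nrow(windows), ")")
  }
  ids <- session$meta$unit_id
  M <- vapply(session$trains[ids], function(tr) {
    vapply(seq_len(nrow(windows)), function(w)
      count_in(tr$spike_times, windows[w, 1], windows[w, 2]), 0)
  }, numeric(nrow(windows)))
  pr <- t(utils::combn(ids, 2))
  noise_r <- vapply(seq_len(nrow(pr)), function(k) {
    x <- M[, pr[k, 1]]; y <- M[, pr[k, 2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  data.frame(unit_a = pr[, 1], unit_b = pr[, 2], noise_r = noise_r,
             n_windows = nrow(windows))
}

#' Expected noise correlation under a shared multiplicative gain
#'
#' Closed form for two conditionally independent Poisson units with rates
#' `mu_i`, `mu_j` (Hz) counted over windows of length `T_s`, modulated by a
#' shared gain with mean 1 and coefficient of variation `cv`.
#'
#' @param mu_i,mu_j unit rates (Hz)
#' @param T_s window length (s)
#' @param cv gain coefficient of variation
#' @return expected Pearson correlation of counts
#' @export
expected_shared_gain_noise_r <- function(mu_i, mu_j, T_s, cv) {
  num <- cv^2 * mu_i * mu_j * T_s^2
  den <- sqrt((mu_i * T_s + cv^2 * mu_i^2 * T_s^2) *
              (mu_j * T_s + cv^2 * mu_j^2 * T_s^2))
  num / den
}

#' Signal correlations from trial-averaged PSTHs
#'
#' For the indentation class, the trial-averaged response (counts per
#' `psth_bin_ms` bin over `psth_window` relative to onset) is computed per
#' force and concatenated across forces; `signal_r` is the Pearson
#' correlation of the concatenated mean-response vectors for each pair. For
#' the brush class the brush epoch is binned directly.
#'
#' @param session a `session`
#' @param stimulus_class `"indentation"` or `"brush"`
#' @param psth_bin_ms PSTH bin width (ms), default 50
#' @param psth_window response window relative to onset (s); default the
#'   full step
#' @return data.frame per pair: `unit_a`, `unit_b`, `signal_r`, `n_bins`,
#'   `stimulus_class`
#' @export
signal_correlations <- function(session, stimulus_class = "indentation",
                                psth_bin_ms = 50, psth_window = NULL) {
  stimulus_class <- match.arg(stimulus_class, c("indentation", "brush"))
  bin_s <- psth_bin_ms / 1000
  ids <- session$meta$unit_id
  if (stimulus_class == "indentation") {
    ind <- session$events[session$events$kind == "indentation", , drop = FALSE]
    forces <- sort(unique(ind$force_mN))
    step <- stats::median(ind$offset_s - ind$onset_s)
    win <- psth_window %||% c(0, step)
    nb <- floor((win[2] - win[1]) / bin_s + 1e-9)
    profiles <- vapply(ids, function(uid) {
      st <- session$trains[[uid]]$spike_times
      unlist(lapply(forces, function(f) {
        on <- ind$onset_s[ind$force_mN == f]
        acc <- numeric(nb)
        for (o in on) {
          acc <- acc + bin_over_windows(st, cbind(o + win[1], o + win[1] + nb * bin_s),
                                        bin_s)$counts
        }
        acc / length(on) / bin_s
      }))
    }, numeric(nb * length(forces)))
  } else {
    br <- session$events[session$events$kind == "brush", , drop = FALSE]
    if (nrow(br) == 0) stop("session has no brush epoch")
    profiles <- vapply(ids, function(uid) {
      bin_over_windows(session$trains[[uid]]$spike_times,
                       cbind(br$onset_s[1], br$offset_s[1]), bin_s)$counts / bin_s
    }, numeric(floor((br$offset_s[1] - br$onset_s[1]) / bin_s + 1e-9)))
  }
  if (nrow(profiles) < 4) stop("fewer than 4 concatenated PSTH bins")
  pr <- t(utils::combn(ids, 2))
  signal_r <- vapply(seq_len(nrow(pr)), function(k) {
    x <- profiles[, pr[k, 1]]; y <- profiles[, pr[k, 2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  data.frame(unit_a = pr[, 1], unit_b = pr[, 2], signal_r = signal_r,
             n_bins = nrow(profiles), stimulus_class = stimulus_class)
}

#' Depth-stratified population coupling
#'
#' Runs [population_coupling()] separately for the superficial
#' (`[0, boundary)` um) and deep strata; both the trigger units and the
#' summed population are restricted to the stratum. A stratum with fewer
#' than `min_units` units is skipped with a warning.
#'
#' @inheritParams population_coupling
#' @return row-bound coupling tables with `stratum` set
#' @export
stratify_coupling <- function(session, bin_ms = 1, epoch = "evoked",
                              n_shuffles = 100, boundary_um = 240, seed,
                              min_units = 5, ...) {
  out <- list()
  for (st in c("superficial", "deep")) {
    n_in <- sum(unit_strata(session, boundary_um) == st)
    if (n_in < min_units) {
      warning("stratum '", st, "' has ", n_in, " < ", min_units,
              " units: skipped")
      next
    }
    out[[st]] <- population_coupling(session, bin_ms = bin_ms, epoch = epoch,
                                     n_shuffles = n_shuffles, stratum = st,
                                     boundary_um = boundary_um,
                                     seed = stream_seed(seed, "stratum", st),
                                     min_units = min_units, ...)
  }
  do.call(rbind, out)
}
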