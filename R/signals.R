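# LFP spectra, extracellular waveform features and clustering, and
# optogenetic tag classification.

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed, mean-detrended
#' segments with 50% overlap; one-sided density normalization.
#'
#' @param x numeric trace
#' @param fs_hz sampling rate
#' @param nperseg segment length; default the power of two nearest 2 s
#' @param overlap fractional overlap, default 0.5
#' @return list: `freq_hz`, `psd`
#' @export
welch_psd <- function(x, fs_hz, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  nperseg <- nperseg %||% min(2^round(log2(2 * fs_hz)), n)
  nperseg <- min(nperseg, n)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))  # Hann
  scale <- fs_hz * sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nf])^2 / scale
    sp[2:(nf - 1)] <- 2 * sp[2:(nf - 1)]
    if (nperseg %% 2 != 0) sp[nf] <- 2 * sp[nf]
    acc <- acc + sp
  }
  list(freq_hz = seq(0, nf - 1) * fs_hz / nperseg, psd = acc / length(starts))
}

#' LFP spectrum and relative band power
#'
#' Each channel is zero-phase low-pass filtered (Butterworth, forward and
#' backward), a Welch PSD is computed per channel and averaged, and the
#' relative band power is the trapezoid integral of the PSD over `band`
#' divided by the integral over `(0, lowpass_hz]` — for the 30-80 Hz band
#' this is the relative gamma power.
#'
#' @param traces numeric vector or samples x channels matrix
#' @param fs_hz sampling rate; must exceed `2 * lowpass_hz`
#' @param lowpass_hz low-pass corner (Hz), default 250
#' @param filter_order Butterworth order, default 8
#' @param band band of interest (Hz), default `c(30, 80)`
#' @param nperseg Welch segment length (see [welch_psd()])
#' @return list of class `lfp_result`: `freq_hz`, `psd` (channel-averaged),
#'   `psd_by_channel`, `relative_band_power`, `band`
#' @export
lfp_spectrum <- function(traces, fs_hz, lowpass_hz = 250, filter_order = 8,
                         band = c(30, 80), nperseg = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  if (fs_hz <= 2 * lowpass_hz) stop("fs_hz must exceed 2 * lowpass_hz")
  if (nrow(traces) / fs_hz < 10) stop("trace must be at least 10 s long")
  if (band[1] <= 0 || band[2] > lowpass_hz) {
    stop("band must lie within (0, lowpass_hz]")
  }
  bf <- signal::butter(filter_order, lowpass_hz / (fs_hz / 2), type = "low")
  psds <- apply(traces, 2, function(ch) {
    filt <- signal::filtfilt(bf, ch)
    welch_psd(filt, fs_hz, nperseg = nperseg)$psd
  })
  freq <- welch_psd(traces[, 1], fs_hz, nperseg = nperseg)$freq_hz
  psd <- rowMeans(psds)
  sel_tot <- freq > 0 & freq <= lowpass_hz
  sel_band <- freq >= band[1] & freq <= band[2]
  rel <- trapz_int(freq[sel_band], psd[sel_band]) /
    trapz_int(freq[sel_tot], psd[sel_tot])
  structure(list(freq_hz = freq, psd = psd, psd_by_channel = psds,
                 relative_band_power = rel, band = band),
            class = "lfp_result")
}

#' Extracellular waveform features
#'
#' The trough is the global minimum; the peak is the maximum after the
#' trough. Features: trough-to-peak duration (ms), trough-to-peak amplitude
#' ratio (|trough| / |peak|), and the repolarization slope — the slope of a
#' linear fit over `slope_window_ms` after the peak (amplitude units per
#' ms). Waveforms with no post-trough peak return `NA` features and are
#' flagged.
#'
#' @param waveform numeric vector of samples
#' @param fs_hz sampling rate (Hz)
#' @param slope_window_ms post-peak fit window, default 0.5
#' @return list: `trough_to_peak_ms`, `trough_to_peak_ratio`,
#'   `repolarization_slope`, `flagged`
#' @export
waveform_features <- function(waveform, fs_hz, slope_window_ms = 0.5) {
  it <- which.min(waveform)
  if (it >= length(waveform)) {
    return(list(trough_to_peak_ms = NA_real_, trough_to_peak_ratio = NA_real_,
                repolarization_slope = NA_real_, flagged = TRUE))
  }
  post <- waveform[(it + 1):length(waveform)]
  ip <- it + which.max(post)
  if (waveform[ip] <= 0) {
    return(list(trough_to_peak_ms = NA_real_, trough_to_peak_ratio = NA_real_,
                repolarization_slope = NA_real_, flagged = TRUE))
  }
  dur_ms <- (ip - it) / fs_hz * 1000
  ratio <- abs(waveform[it]) / abs(waveform[ip])
  ns <- max(2, round(slope_window_ms / 1000 * fs_hz))
  iend <- min(length(waveform), ip + ns)
  seg <- waveform[ip:iend]
  t_ms <- (seq_along(seg) - 1) / fs_hz * 1000
  slope <- unname(stats::coef(stats::lm(seg ~ t_ms))[2])
  list(trough_to_peak_ms = dur_ms, trough_to_peak_ratio = ratio,
       repolarization_slope = slope, flagged = FALSE)
}

#' Feature table for a set of waveforms
#'
#' @param waveforms matrix, one waveform per row
#' @param fs_hz sampling rate
#' @return data.frame of [waveform_features()] per row
#' @export
waveform_feature_table <- function(waveforms, fs_hz) {
  do.call(rbind, lapply(seq_len(nrow(waveforms)), function(i) {
    as.data.frame(waveform_features(waveforms[i, ], fs_hz))
  }))
}

#' K-means clustering of waveform features
#'
#' Features are standardized to zero mean and unit variance, then clustered
#' with k-means (k-means++-style multiple restarts via `nstart`, best
#' within-cluster sum of squares kept). Degenerate inputs in which all
#' feature rows coincide are assigned a single cluster and flagged.
#'
#' @param features data.frame or matrix of numeric features (rows = units)
#' @param k number of clusters, default 3
#' @param n_restarts restarts, default 20
#' @param seed integer seed
#' @return list: `cluster` (integer assignments), `centers` (standardized),
#'   `tot_withinss`, `degenerate`
#' @export
cluster_waveforms <- function(features, k = 3, n_restarts = 20, seed) {
  if (missing(seed)) stop("seed is required")
  X <- as.matrix(features)
  ok <- stats::complete.cases(X)
  if (sum(ok) < k) stop("fewer units with valid features (", sum(ok),
                        ") than clusters (", k, ")")
  Xs <- X[ok, , drop = FALSE]
  sds <- apply(Xs, 2, stats::sd)
  Xs <- sweep(Xs, 2, colMeans(Xs))
  Xs[, sds > 0] <- sweep(Xs[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  if (nrow(unique(Xs)) < k) {
    cl <- rep(NA_integer_, nrow(X))
    cl[ok] <- 1L
    return(list(cluster = cl, centers = NULL, tot_withinss = 0,
                degenerate = TRUE))
  }
  km <- withr::with_seed(seed,
    stats::kmeans(Xs, centers = k, nstart = n_restarts, iter.max = 100))
  cl <- rep(NA_integer_, nrow(X))
  cl[ok] <- km$cluster
  list(cluster = cl, centers = km$centers, tot_withinss = km$tot.withinss,
       degenerate = FALSE)
}

#' Opto-tag classification
#'
#' A unit is opto-tagged when it is responsive to light pulses both before
#' and after the glutamatergic blocker (direct, not synaptically relayed),
#' its median light-evoked first-spike latency is below 10 ms, and its
#' spike jitter is low. Responsiveness per block uses the same
#' shuffled-null envelope machinery as [latency_and_jitter()], applied to
#' the light-aligned cumulative first-spike curve within the response
#' window.
#'
#' @param train a `spike_train`
#' @param pulses_pre,pulses_post light pulse onset times (s) before / after
#'   the blocker; `pulses_post = NULL` marks a missing block
#' @param response_window_ms latency criterion and search window (ms),
#'   default 10
#' @param jitter_max_ms maximum jitter for tagging (ms), default 3
#' @param n_shuffles shuffle count
#' @param alpha test level
#' @param seed integer seed
#' @param pre_s shuffle window extent before each pulse (s)
#' @param min_pulses minimum pulses per block, default 25
#' @return list of class `optotag_result`: `responsive_pre`,
#'   `responsive_post`, `median_latency_ms`, `jitter_ms`, `tagged`
#'   (`NA` with a `reason` when the post block is missing)
#' @export
classify_optotag <- function(train, pulses_pre, pulses_post,
                             response_window_ms = 10, jitter_max_ms = 3,
                             n_shuffles = 100, alpha = 0.05, seed,
                             pre_s = 0.1, min_pulses = 25) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (length(pulses_pre) < min_pulses) {
    stop("need at least ", min_pulses, " pulses in the pre-blocker block")
  }
  win_s <- response_window_ms / 1000
  env_pre <- first_spike_envelope(train, pulses_pre, win_s = win_s,
                                  pre_s = pre_s, bin_s = 0.001,
                                  n_shuffles = n_shuffles, alpha = alpha,
                                  seed = stream_seed(seed, "opto", 1))
  responsive_pre <- !is.na(env_pre$latency_s)
  if (is.null(pulses_post) || length(pulses_post) == 0) {
    return(structure(list(responsive_pre = responsive_pre,
                          responsive_post = NA, median_latency_ms = NA_real_,
                          jitter_ms = NA_real_, tagged = NA,
                          reason = "missing post-blocker block"),
                     class = "optotag_result"))
  }
  if (length(pulses_post) < min_pulses) {
    stop("need at least ", min_pulses, " pulses in the post-blocker block")
  }
  env_post <- first_spike_envelope(train, pulses_post, win_s = win_s,
                                   pre_s = pre_s, bin_s = 0.001,
                                   n_shuffles = n_shuffles, alpha = alpha,
                                   seed = stream_seed(seed, "opto", 2))
  responsive_post <- !is.na(env_post$latency_s)
  lats <- c(env_pre$latencies_s, env_post$latencies_s) * 1000
  lats <- lats[!is.na(lats)]
  med <- if (length(lats)) stats::median(lats) else NA_real_
  jit <- if (length(lats) > 1) stats::sd(lats) else NA_real_
  tagged <- isTRUE(responsive_pre) && isTRUE(responsive_post) &&
    !is.na(med) && med < 10 && !is.na(jit) && jit <= jitter_max_ms
  structure(list(responsive_pre = responsive_pre,
                 responsive_post = responsive_post,
                 median_latency_ms = med, jitter_ms = jit, tagged = tagged,
                 reason = NA_character_),
            class = "optotag_result")
}
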