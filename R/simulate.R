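# Synthetic session generator: inhomogeneous-Poisson spike trains with
# injected population-event synchrony, shared trial gain, tuning templates,
# forced first-spike latencies, and optional brush / light-pulse blocks.

#' Stimulation protocol specification
#'
#' Describes the trial structure the generator lays out: an optional leading
#' stimulus-free block, then interleaved 500 ms indentation steps (each
#' preceded by a 1.5 s baseline), then an optional brush epoch and optional
#' light-pulse blocks before and after a glutamatergic blocker.
#'
#' @param forces_mN ascending innocuous forces in \[1, 75\] mN
#' @param step_dur_s indentation step duration (s)
#' @param baseline_s pre-stimulus baseline per trial (s); at least 1.5
#' @param trials_per_force trials delivered at each force
#' @param post_s quiet time after each step before the next baseline (s)
#' @param spont_dur_s leading stimulus-free block (s)
#' @param brush_dur_s brush epoch duration (s); 0 disables
#' @param n_light_pulses light pulses per block (pre- and post-blocker);
#'   0 disables
#' @param light_width_ms pulse width, 1-20 ms
#' @param light_period_s pulse spacing (s)
#' @return object of class `protocol_spec`
#' @export
protocol_spec <- function(forces_mN = c(1, 5, 10, 20, 45, 75),
                          step_dur_s = 0.5, baseline_s = 1.5,
                          trials_per_force = 10, post_s = 0.55,
                          spont_dur_s = 0, brush_dur_s = 0,
                          n_light_pulses = 0, light_width_ms = 5,
                          light_period_s = 0.25) {
  if (length(forces_mN) && (is.unsorted(forces_mN, strictly = TRUE) ||
                            any(forces_mN < 1) || any(forces_mN > 75))) {
    stop("forces_mN must be strictly ascending within [1, 75]")
  }
  if (baseline_s < 1.5) stop("baseline_s must be >= 1.5 s")
  if (n_light_pulses > 0 && (light_width_ms < 1 || light_width_ms > 20)) {
    stop("light_width_ms must lie in [1, 20]")
  }
  structure(as.list(environment()), class = "protocol_spec")
}

#' Population specification for the generator
#'
#' Per-unit parameters are recycled from scalars to `n_units`. Conditional
#' on the population-event train and the per-trial gain, units are
#' independent inhomogeneous Poisson processes with rate
#' `g_t * [b + 1(F >= theta) * w(F) * (A_on a_on(tau) + A_sus box(tau) +
#' A_off a_off(tau))]`, where `a_on`/`a_off` are alpha kernels (peak 1) and
#' `box` spans the step. Synchrony is injected by a population-event train:
#' at each event a unit emits one spike with probability `p_event`, jittered
#' by a zero-mean Gaussian with SD `sigma_sync_ms`. Tuning similarity is
#' controlled by `rho`, the weight mixing a shared force-tuning template
#' with a private one.
#'
#' @param n_units number of units
#' @param depth_um vector of recording depths in \[0, 620\] um
#' @param b_hz baseline rate per unit (Hz)
#' @param theta_mN force threshold per unit (mN; `Inf` = never responds)
#' @param A_on,A_sus,A_off evoked kernel amplitudes (Hz above baseline)
#' @param tau_on_ms,tau_off_ms alpha-kernel time constants (ms)
#' @param p_event per-unit event-participation probability in \[0, 1\]
#' @param sigma_sync_ms event timing jitter SD (ms)
#' @param event_rate_hz population-event rate during each trial's response
#'   span (onset to offset + 50 ms)
#' @param event_rate_spont_hz event rate during the leading stimulus-free
#'   block
#' @param event_rate_brush_hz event rate during the brush epoch
#' @param gain_cv coefficient of variation of the lognormal trial-shared
#'   gain (mean 1)
#' @param rho tuning-template mixing weight in \[0, 1\]; 1 = identical
#'   force tuning across units
#' @param tuning_weights optional explicit n_units x n_forces matrix of
#'   tuning weights, overriding the template mix
#' @param latency_mu_ms,latency_sd_ms per-unit forced first-spike latency
#'   mean and SD for the ON response (ms); `NA` disables forcing
#' @param brush_rate_hz evoked rate above baseline during brush (Hz)
#' @param light_latency_ms per-unit light-response latency (ms; `NA` = not
#'   light responsive); responsive units emit one spike per pulse at this
#'   latency plus Gaussian jitter
#' @param light_jitter_ms SD of the light-response jitter (ms)
#' @param light_resp_post logical per unit: still responsive after the
#'   glutamatergic blocker (direct, not relayed)
#' @return object of class `population_spec`
#' @export
population_spec <- function(n_units, depth_um = NULL, b_hz = 5,
                            theta_mN = 10, A_on = 30, A_sus = 15, A_off = 20,
                            tau_on_ms = 10, tau_off_ms = 10,
                            p_event = 0, sigma_sync_ms = 1,
                            event_rate_hz = 0, event_rate_spont_hz = 0,
                            event_rate_brush_hz = 0,
                            gain_cv = 0, rho = 0.5, tuning_weights = NULL,
                            latency_mu_ms = NA, latency_sd_ms = 1,
                            brush_rate_hz = 0,
                            light_latency_ms = NA, light_jitter_ms = 0.5,
                            light_resp_post = TRUE) {
  rec <- function(x) rep_len(x, n_units)
  if (is.null(depth_um)) {
    depth_um <- rep_len(c(seq(40, 230, length.out = ceiling(n_units / 2)),
                          seq(260, 600, length.out = floor(n_units / 2))), n_units)
  }
  spec <- list(n_units = n_units, depth_um = rec(depth_um), b_hz = rec(b_hz),
               theta_mN = rec(theta_mN), A_on = rec(A_on), A_sus = rec(A_sus),
               A_off = rec(A_off), tau_on_ms = tau_on_ms, tau_off_ms = tau_off_ms,
               p_event = rec(p_event), sigma_sync_ms = sigma_sync_ms,
               event_rate_hz = event_rate_hz,
               event_rate_spont_hz = event_rate_spont_hz,
               event_rate_brush_hz = event_rate_brush_hz,
               gain_cv = gain_cv, rho = rho, tuning_weights = tuning_weights,
               latency_mu_ms = rec(latency_mu_ms), latency_sd_ms = rec(latency_sd_ms),
               brush_rate_hz = rec(brush_rate_hz),
               light_latency_ms = rec(light_latency_ms),
               light_jitter_ms = light_jitter_ms,
               light_resp_post = rec(light_resp_post))
  if (any(spec$p_event < 0 | spec$p_event > 1)) stop("p_event must lie in [0, 1]")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (any(c(spec$b_hz, spec$A_on, spec$A_sus, spec$A_off) < 0)) {
    stop("rates and amplitudes must be >= 0")
  }
  if (any(spec$depth_um < 0 | spec$depth_um > 620)) {
    stop("depth_um must lie in [0, 620]")
  }
  structure(spec, class = "population_spec")
}

# Alpha kernel with unit peak at tau_ms.
.alpha_kernel <- function(t, tau_s) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau_s) * exp(1 - t[pos] / tau_s)
  out
}

# Thinning sampler for one trial window of one unit. rate_fn maps time
# relative to onset to Hz; lambda_max must bound it.
.thin_sample <- function(t0, t1, rate_fn, lambda_max) {
  if (lambda_max <= 0) return(numeric())
  n <- stats::rpois(1, lambda_max * (t1 - t0))
  if (n == 0) return(numeric())
  tt <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rate_fn(tt) / lambda_max
  tt[keep]
}

#' Simulate a session with ground truth
#'
#' Lays out the protocol timeline, draws private inhomogeneous-Poisson
#' spikes by thinning, injects population-event spikes, applies the shared
#' lognormal trial gain, forces ON first-spike latencies where configured,
#' then merges, sorts and deduplicates spikes at the 50 microsecond sampling
#' resolution. All randomness flows from `seed` through named streams keyed
#' by unit and trial, so enlarging the population leaves existing units'
#' spikes unchanged.
#'
#' @param protocol a [protocol_spec()]
#' @param pop a [population_spec()]
#' @param seed integer seed (mandatory)
#' @param session_id,condition labels stored in the session
#' @return list with elements `session` and `ground_truth`
#' @export
simulate_session <- function(protocol, pop, seed, session_id = "sim",
                             condition = "synthetic") {
  if (missing(seed) || is.null(seed)) stop("seed is required for simulation")
  stopifnot(inherits(protocol, "protocol_spec"), inherits(pop, "population_spec"))
  P <- protocol
  n_trials <- length(P$forces_mN) * P$trials_per_force
  slot <- P$baseline_s + P$step_dur_s + P$post_s
  t0_trials <- P$spont_dur_s
  onsets <- if (n_trials > 0) t0_trials + (seq_len(n_trials) - 1) * slot + P$baseline_s else numeric()
  forces <- rep(P$forces_mN, P$trials_per_force)  # interleaved sweeps
  offsets <- onsets + P$step_dur_s
  t_ind_end <- if (n_trials > 0) max(offsets) + P$post_s else t0_trials
  brush_on <- t_ind_end
  brush_off <- brush_on + P$brush_dur_s
  t_light0 <- brush_off + 1
  light_on_pre <- light_on_post <- numeric()
  if (P$n_light_pulses > 0) {
    light_on_pre <- t_light0 + (seq_len(P$n_light_pulses) - 1) * P$light_period_s
    light_on_post <- max(light_on_pre) + 5 + (seq_len(P$n_light_pulses) - 1) * P$light_period_s
  }
  t_stop <- max(c(t_ind_end, brush_off, light_on_post + 1, light_on_pre + 1,
                  P$spont_dur_s)) + 1

  n <- pop$n_units
  tau_on <- pop$tau_on_ms / 1000
  tau_off <- pop$tau_off_ms / 1000

  # force-tuning weights: rho-weighted mix of a shared saturating template
  # and a private random template, both scaled to peak 1
  nf <- length(P$forces_mN)
  if (!is.null(pop$tuning_weights)) {
    W <- pop$tuning_weights
    stopifnot(nrow(W) == n, ncol(W) == nf)
  } else if (nf > 0) {
    shared <- sqrt(P$forces_mN / max(P$forces_mN))
    W <- t(vapply(seq_len(n), function(i) {
      priv <- with_stream(seed, "tuning", i, expr = stats::runif(nf, 0.2, 1))
      w <- pop$rho * shared + (1 - pop$rho) * priv
      w / max(w)
    }, numeric(nf)))
  } else {
    W <- matrix(0, n, 0)
  }

  # shared per-trial gain (lognormal, mean 1)
  g <- rep(1, n_trials)
  if (pop$gain_cv > 0 && n_trials > 0) {
    s2 <- log(1 + pop$gain_cv^2)
    g <- with_stream(seed, "gain",
                     expr = stats::rlnorm(n_trials, -s2 / 2, sqrt(s2)))
  }

  # population-event train over response spans / spont block / brush
  ev_windows <- NULL
  ev_rates <- NULL
  if (pop$event_rate_hz > 0 && n_trials > 0) {
    ev_windows <- rbind(ev_windows, cbind(onsets, offsets + 0.05))
    ev_rates <- c(ev_rates, rep(pop$event_rate_hz, n_trials))
  }
  if (pop$event_rate_spont_hz > 0 && P$spont_dur_s > 0) {
    ev_windows <- rbind(ev_windows, cbind(0, P$spont_dur_s))
    ev_rates <- c(ev_rates, pop$event_rate_spont_hz)
  }
  if (pop$event_rate_brush_hz > 0 && P$brush_dur_s > 0) {
    ev_windows <- rbind(ev_windows, cbind(brush_on, brush_off))
    ev_rates <- c(ev_rates, pop$event_rate_brush_hz)
  }
  events_t <- numeric()
  if (!is.null(ev_windows)) {
    events_t <- with_stream(seed, "events", expr = {
      out <- numeric()
      for (w in seq_len(nrow(ev_windows))) {
        len <- ev_windows[w, 2] - ev_windows[w, 1]
        k <- stats::rpois(1, ev_rates[w] * len)
        out <- c(out, stats::runif(k, ev_windows[w, 1], ev_windows[w, 2]))
      }
      sort(out)
    })
  }

  trains <- vector("list", n)
  sig_s <- pop$sigma_sync_ms / 1000
  for (i in seq_len(n)) {
    spikes <- numeric()
    # private spikes, trial by trial (gain applies to the whole trial window)
    if (n_trials > 0) {
      for (tr in seq_len(n_trials)) {
        on <- onsets[tr]
        responds <- forces[tr] >= pop$theta_mN[i]
        w_f <- if (responds) W[i, match(forces[tr], P$forces_mN)] else 0
        rate_fn <- function(tt) {
          tau <- tt - on
          r <- rep(pop$b_hz[i], length(tt))
          if (responds) {
            r <- r + w_f * (pop$A_on[i] * .alpha_kernel(tau, tau_on) +
                            pop$A_sus[i] * as.numeric(tau > 0 & tau <= P$step_dur_s) +
                            pop$A_off[i] * .alpha_kernel(tau - P$step_dur_s, tau_off))
          }
          g[tr] * r
        }
        lmax <- g[tr] * (pop$b_hz[i] +
                         w_f * (max(pop$A_on[i], pop$A_off[i]) + pop$A_sus[i]))
        sp <- with_stream(seed, "unit_trial", i, tr, expr = .thin_sample(
          on - P$baseline_s, on + P$step_dur_s + P$post_s, rate_fn, lmax))
        # forced ON first-spike latency
        if (responds && !is.na(pop$latency_mu_ms[i])) {
          L <- with_stream(seed, "latency", i, tr, expr = stats::rnorm(
            1, pop$latency_mu_ms[i], pop$latency_sd_ms[i])) / 1000
          L <- max(L, 1e-4)
          if (!any(sp > on & sp <= on + L)) sp <- c(sp, on + L)
        }
        spikes <- c(spikes, sp)
      }
    }
    # private spikes in spont / brush / light blocks
    if (P$spont_dur_s > 0) {
      spikes <- c(spikes, with_stream(seed, "unit_block", i, 1, expr =
        .thin_sample(0, P$spont_dur_s, function(tt) rep(pop$b_hz[i], length(tt)),
                     pop$b_hz[i])))
    }
    if (P$brush_dur_s > 0) {
      rb <- pop$b_hz[i] + pop$brush_rate_hz[i]
      spikes <- c(spikes, with_stream(seed, "unit_block", i, 2, expr =
        .thin_sample(brush_on, brush_off, function(tt) rep(rb, length(tt)), rb)))
    }
    if (P$n_light_pulses > 0) {
      spikes <- c(spikes, with_stream(seed, "unit_block", i, 3, expr =
        .thin_sample(t_light0 - 1, t_stop - 0.5,
                     function(tt) rep(pop$b_hz[i], length(tt)), pop$b_hz[i])))
      if (!is.na(pop$light_latency_ms[i])) {
        pulses <- c(light_on_pre,
                    if (pop$light_resp_post[i]) light_on_post else numeric())
        lj <- with_stream(seed, "light", i, expr = stats::rnorm(
          length(pulses), pop$light_latency_ms[i], pop$light_jitter_ms)) / 1000
        spikes <- c(spikes, pulses + pmax(lj, 1e-4))
      }
    }
    # population-event spikes
    if (length(events_t) > 0 && pop$p_event[i] > 0) {
      ev_sp <- with_stream(seed, "event_unit", i, expr = {
        take <- stats::runif(length(events_t)) < pop$p_event[i]
        events_t[take] + stats::rnorm(sum(take), 0, sig_s)
      })
      spikes <- c(spikes, ev_sp)
    }
    spikes <- sort(spikes)
    spikes <- spikes[spikes > 0 & spikes < t_stop]
    if (length(spikes) > 1) {
      keep <- c(TRUE, diff(spikes) >= 50e-6)
      spikes <- spikes[keep]
    }
    trains[[i]] <- spike_train(sprintf("u%02d", i), spikes, t_stop)
  }
  names(trains) <- vapply(trains, `[[`, "", "unit_id")

  meta <- data.frame(unit_id = names(trains), depth_um = pop$depth_um,
                     channel = seq_len(n), stringsAsFactors = FALSE)
  ev <- data.frame(kind = character(), onset_s = numeric(), offset_s = numeric(),
                   force_mN = numeric(), block = character(),
                   trial_index = integer(), stringsAsFactors = FALSE)
  if (n_trials > 0) {
    ev <- rbind(ev, data.frame(kind = "indentation", onset_s = onsets,
                               offset_s = offsets, force_mN = forces,
                               block = NA_character_,
                               trial_index = seq_len(n_trials)))
  }
  if (P$brush_dur_s > 0) {
    ev <- rbind(ev, data.frame(kind = "brush", onset_s = brush_on,
                               offset_s = brush_off, force_mN = NA_real_,
                               block = NA_character_, trial_index = n_trials + 1L))
  }
  if (P$n_light_pulses > 0) {
    wd <- P$light_width_ms / 1000
    ev <- rbind(ev,
      data.frame(kind = "light", onset_s = light_on_pre,
                 offset_s = light_on_pre + wd, force_mN = NA_real_,
                 block = "pre_blocker",
                 trial_index = n_trials + 1L + seq_along(light_on_pre)),
      data.frame(kind = "light", onset_s = light_on_post,
                 offset_s = light_on_post + wd, force_mN = NA_real_,
                 block = "post_blocker",
                 trial_index = n_trials + 1L + P$n_light_pulses + seq_along(light_on_post)))
  }

  gt <- list(unit_id = names(trains), p_event = pop$p_event,
             theta_mN = pop$theta_mN, b_hz = pop$b_hz,
             A_on = pop$A_on, A_sus = pop$A_sus, A_off = pop$A_off,
             latency_mu_ms = pop$latency_mu_ms, latency_sd_ms = pop$latency_sd_ms,
             gain_cv = pop$gain_cv, rho = pop$rho,
             sigma_sync_ms = pop$sigma_sync_ms, depth_um = pop$depth_um,
             rng_seed = seed)
  s <- session(session_id = session_id, trains = trains, meta = meta,
               events = ev, condition = condition, ground_truth = gt,
               spont_dur_s = P$spont_dur_s)
  list(session = s, ground_truth = gt)
}

#' Preset experimental conditions
#'
#' Named parameterizations emulating the directional phenotypes of the
#' experimental groups: `sham_like` is the reference; `sni_like` halves
#' superficial event participation, reduces sustained amplitude by 30% and
#' doubles latency SD (superficial desynchronization with weakened sustained
#' firing); `pv_silenced_like` raises baseline and evoked rates 30% and
#' halves participation (disinhibition with degraded coordination);
#' `psi_ko_like` raises rates 30%, raises participation 50% and lowers every
#' force threshold by one step (hyperexcitable, hypersynchronous,
#' sensitized). Base parameter draws depend only on the seed, so presets
#' sharing a seed have matched units.
#'
#' @param name one of `"sham_like"`, `"sni_like"`, `"pv_silenced_like"`,
#'   `"psi_ko_like"`
#' @param seed integer seed
#' @param n_units units per session (half superficial, half deep)
#' @param trials_per_force indentation trials per force
#' @param protocol optional [protocol_spec()] override
#' @return list with `session` and `ground_truth`
#' @export
preset_condition <- function(name, seed, n_units = 16, trials_per_force = 12,
                             protocol = NULL) {
  presets <- c("sham_like", "sni_like", "pv_silenced_like", "psi_ko_like")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ", paste(presets, collapse = ", "))
  }
  P <- protocol %||% protocol_spec(trials_per_force = trials_per_force)
  nf <- length(P$forces_mN)
  base <- with_stream(seed, "preset", expr = {
    ns <- ceiling(n_units / 2)
    list(depth = c(stats::runif(ns, 20, 239), stats::runif(n_units - ns, 241, 600)),
         b = stats::runif(n_units, 2, 8),
         theta_idx = sample(seq_len(min(4, nf)), n_units, replace = TRUE),
         lat_mu = stats::runif(n_units, 8, 15))
  })
  superficial <- base$depth < 240
  b <- base$b; theta_idx <- base$theta_idx
  A_on <- rep(30, n_units); A_sus <- rep(15, n_units); A_off <- rep(20, n_units)
  p <- rep(0.3, n_units); lat_sd <- rep(1.5, n_units)
  if (name == "sni_like") {
    p[superficial] <- p[superficial] / 2
    A_sus <- A_sus * 0.7
    lat_sd <- lat_sd * 2
  } else if (name == "pv_silenced_like") {
    b <- b * 1.3; A_on <- A_on * 1.3; A_sus <- A_sus * 1.3; A_off <- A_off * 1.3
    p <- p / 2
  } else if (name == "psi_ko_like") {
    b <- b * 1.3
    p <- pmin(1, p * 1.5)
    theta_idx <- pmax(1L, theta_idx - 1L)
  }
  pop <- population_spec(
    n_units = n_units, depth_um = base$depth, b_hz = b,
    theta_mN = P$forces_mN[theta_idx], A_on = A_on, A_sus = A_sus,
    A_off = A_off, p_event = p, sigma_sync_ms = 1, event_rate_hz = 8,
    gain_cv = 0.2, rho = 0.6, latency_mu_ms = base$lat_mu,
    latency_sd_ms = lat_sd, brush_rate_hz = 10,
    event_rate_brush_hz = if (P$brush_dur_s > 0) 4 else 0)
  out <- simulate_session(P, pop, seed = stream_seed(seed, "sim", name),
                          session_id = paste0(name, "_", seed), condition = name)
  out$ground_truth$preset <- name
  out$session$ground_truth$preset <- name
  out
}

#' Simulate labeled extracellular waveforms
#'
#' Biphasic templates (Gaussian trough followed by a Gaussian peak) sampled
#' at `fs_hz`, plus white noise; class labels are retained for clustering
#' recovery tests.
#'
#' @param n_per_class waveforms per class
#' @param classes list of template specs; each a list with
#'   `trough_to_peak_ms` and optional `amp_trough`, `amp_peak`,
#'   `trough_w_ms`, `peak_w_ms`
#' @param noise_sd white-noise SD (same units as amplitudes)
#' @param seed integer seed
#' @param fs_hz sampling rate (default 20 kHz)
#' @param dur_ms waveform snippet length
#' @return list: `waveforms` (matrix, one row per waveform), `labels`
#'   (0-based class labels), `fs_hz`
#' @export
simulate_waveforms <- function(n_per_class, classes, noise_sd = 0, seed,
                               fs_hz = 20000, dur_ms = 2.4) {
  if (missing(seed)) stop("seed is required")
  if (length(classes) < 1) stop("at least one class template is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_samp <- round(dur_ms / 1000 * fs_hz)
  t_ms <- (seq_len(n_samp) - 1) / fs_hz * 1000
  trough_ms <- 0.6
  tmpl <- lapply(classes, function(cl) {
    at <- cl$amp_trough %||% 1
    ap <- cl$amp_peak %||% 0.4
    tw <- cl$trough_w_ms %||% 0.08
    pw <- cl$peak_w_ms %||% 0.3
    # snap trough and peak onto the sample grid so durations are exact
    it <- round(trough_ms / 1000 * fs_hz)
    ip <- it + round(cl$trough_to_peak_ms / 1000 * fs_hz)
    tt <- it / fs_hz * 1000
    tp <- ip / fs_hz * 1000
    -at * exp(-(t_ms - tt)^2 / (2 * tw^2)) + ap * exp(-(t_ms - tp)^2 / (2 * pw^2))
  })
  withr::with_seed(seed, {
    wf <- do.call(rbind, lapply(seq_along(tmpl), function(k) {
      m <- matrix(rep(tmpl[[k]], each = n_per_class), nrow = n_per_class)
      m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = n_per_class)
    }))
  })
  list(waveforms = wf, labels = rep(seq_along(classes) - 1L, each = n_per_class),
       fs_hz = fs_hz)
}

#' Simulate an LFP trace
#'
#' Gaussian noise with a 1/f power spectrum (flat below 1 Hz) plus an
#' optional sinusoid in the gamma band. Spectral shaping is done in the
#' Fourier domain: amplitude at frequency f is proportional to
#' `1/sqrt(max(f, 1))`.
#'
#' @param dur_s duration (s)
#' @param fs_hz sampling rate, >= 1000
#' @param one_over_f_amp amplitude scale of the 1/f component
#' @param gamma_hz sinusoid frequency in (0, fs/2); `NULL` disables
#' @param gamma_amp sinusoid amplitude
#' @param seed integer seed
#' @return numeric trace of length `dur_s * fs_hz`
#' @export
simulate_lfp <- function(dur_s, fs_hz = 1000, one_over_f_amp = 1,
                         gamma_hz = NULL, gamma_amp = 0, seed) {
  if (missing(seed)) stop("seed is required")
  if (fs_hz < 1000) stop("fs_hz must be >= 1000")
  if (!is.null(gamma_hz) && (gamma_hz <= 0 || gamma_hz >= fs_hz / 2)) {
    stop("gamma_hz must lie in (0, fs/2)")
  }
  n <- round(dur_s * fs_hz)
  x <- withr::with_seed(seed, {
    if (one_over_f_amp > 0) {
      f <- seq(0, fs_hz / 2, length.out = floor(n / 2) + 1)
      amp <- one_over_f_amp / sqrt(pmax(f, 1))
      amp[1] <- 0
      half <- amp * (stats::rnorm(length(f)) + 1i * stats::rnorm(length(f)))
      spec <- c(half, Conj(rev(half[2:(length(half) - if (n %% 2 == 0) 1 else 0)])))
      Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
    } else {
      numeric(n)
    }
  })
  if (!is.null(gamma_hz) && gamma_amp > 0) {
    tt <- (seq_len(n) - 1) / fs_hz
    x <- x + gamma_amp * sin(2 * pi * gamma_hz * tt)
  }
  x
}
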