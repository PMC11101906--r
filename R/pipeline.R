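# Config-driven end-to-end runs and the group-contrast harness.

#' Per-session summary metrics
#'
#' One row of scalar metrics per session, used by the group contrast:
#' mean population coupling (all units and superficial stratum), mean
#' baseline-subtracted sustained rate at the highest force, mean response
#' threshold over units with a threshold, and mean pairwise lag-0
#' synchrony.
#'
#' @param session a `session`
#' @param seed integer seed for the stochastic stages
#' @param bin_ms coupling/synchrony bin (ms)
#' @param n_shuffles coupling shuffle count
#' @param n_boot threshold bootstrap count
#' @param boundary_um depth stratum boundary
#' @param metrics subset of `c("coupling", "sustained_rate", "threshold",
#'   "sync_r")`
#' @return one-row data.frame
#' @export
session_metrics <- function(session, seed, bin_ms = 1, n_shuffles = 100,
                            n_boot = 1000, boundary_um = 240,
                            metrics = c("coupling", "sustained_rate",
                                        "threshold", "sync_r")) {
  ev <- session$events
  ind <- ev[ev$kind == "indentation", , drop = FALSE]
  out <- data.frame(session_id = session$session_id,
                    condition = session$condition)
  if ("coupling" %in% metrics) {
    cp <- population_coupling(session, bin_ms = bin_ms, epoch = "evoked",
                              n_shuffles = n_shuffles,
                              seed = stream_seed(seed, "m_coupling"))
    out$coupling_hz <- mean(cp$coupling_hz, na.rm = TRUE)
    strata <- unit_strata(session, boundary_um)
    sup_ids <- names(strata)[strata == "superficial"]
    out$coupling_superficial_hz <- if (length(sup_ids) >= 5) {
      cps <- population_coupling(session, bin_ms = bin_ms, epoch = "evoked",
                                 n_shuffles = n_shuffles,
                                 stratum = "superficial",
                                 boundary_um = boundary_um,
                                 seed = stream_seed(seed, "m_coupling_sup"))
      mean(cps$coupling_hz, na.rm = TRUE)
    } else NA_real_
  }
  if ("sustained_rate" %in% metrics && nrow(ind) > 0) {
    fmax <- max(ind$force_mN)
    tr <- ind[ind$force_mN == fmax, , drop = FALSE]
    sus <- vapply(session$trains, function(train) {
      m <- attr(window_rates(train, tr), "means")
      unname(m["sustained_hz"] - m["baseline_hz"])
    }, 0)
    out$sustained_hz <- mean(sus)
  }
  if ("threshold" %in% metrics && nrow(ind) > 0) {
    th <- vapply(seq_along(session$trains), function(i) {
      r <- detect_threshold(session$trains[[i]], ind, n_boot = n_boot,
                            seed = stream_seed(seed, "m_thresh", i))
      r$threshold_mN %||% NA_real_
    }, 0)
    out$threshold_mN <- mean(th, na.rm = TRUE)
    out$n_responsive <- sum(!is.na(th))
  }
  if ("sync_r" %in% metrics) {
    ps <- pairwise_synchrony(session, bin_ms = bin_ms, epoch = "evoked",
                             max_lag_ms = 0)
    out$sync_r <- mean(ps$sync_r, na.rm = TRUE)
  }
  out
}

#' Group contrast over per-session metrics
#'
#' Computes [session_metrics()] for every session of both groups and
#' compares each metric with a two-sided rank-sum test, reporting group
#' means, p, and the direction of the difference (sign of mean(a) -
#' mean(b)). Directions, not magnitudes, are the meaningful output: the
#' magnitudes depend on generator conventions. Per-session values are
#' attached as `attr(, "per_session")` so callers can run directional
#' (one-sided) tests themselves.
#'
#' @param sessions_a,sessions_b lists of `session` objects (at least 3 per
#'   group)
#' @param seed integer seed
#' @param metrics metrics to compare (see [session_metrics()])
#' @param ... passed to [session_metrics()]
#' @return data.frame per metric: `metric`, `mean_a`, `mean_b`, `p`,
#'   `direction`
#' @export
phenotype_contrast <- function(sessions_a, sessions_b, seed,
                               metrics = c("coupling", "sustained_rate",
                                           "threshold", "sync_r"), ...) {
  if (length(sessions_a) < 3 || length(sessions_b) < 3) {
    stop("need at least 3 sessions per group")
  }
  tab <- function(sessions, grp) {
    do.call(rbind, lapply(seq_along(sessions), function(k) {
      m <- session_metrics(sessions[[k]],
                           seed = stream_seed(seed, grp, k),
                           metrics = metrics, ...)
      m$group <- grp
      m
    }))
  }
  per <- rbind(tab(sessions_a, "a"), tab(sessions_b, "b"))
  cols <- setdiff(names(per), c("session_id", "condition", "group",
                                "n_responsive"))
  rows <- lapply(cols, function(cl) {
    va <- per[[cl]][per$group == "a"]
    vb <- per[[cl]][per$group == "b"]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 3 || length(vb) < 3) {
      stop("metric '", cl, "' missing in too many sessions")
    }
    cg <- compare_groups(va, vb, method = "rank_sum")
    data.frame(metric = cl, mean_a = mean(va), mean_b = mean(vb),
               p = cg$p,
               direction = sign(mean(va) - mean(vb)))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_session") <- per
  out
}

#' Run the analysis pipeline on one or more sessions
#'
#' Executes the requested stages in order (tuning, correlations, timing,
#' signals), writing one tidy table per stage per session plus a run log.
#' Stage failures abort with the stage and session named; tables written
#' before the failure are retained next to a `FAILED` marker file.
#'
#' @param sessions list of `session` objects, or a single session
#' @param stages subset of `c("tuning", "correlations", "timing",
#'   "signals")`
#' @param out_dir output directory; `NULL` skips writing
#' @param seed integer seed
#' @param params named list of stage parameter overrides: `bin_ms`,
#'   `n_shuffles`, `n_boot`, `boundary_um`, `latency_forces_mN`,
#'   `band_hz`
#' @return named list of per-stage result tables (invisibly when writing)
#' @export
run_pipeline <- function(sessions, stages = c("tuning", "correlations"),
                         out_dir = NULL, seed, params = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (inherits(sessions, "session")) sessions <- list(sessions)
  stages <- match.arg(stages, c("tuning", "correlations", "timing", "signals"),
                      several.ok = TRUE)
  p <- utils::modifyList(list(bin_ms = 1, n_shuffles = 100, n_boot = 1000,
                              boundary_um = 240,
                              latency_forces_mN = c(10, 75),
                              band_hz = c(30, 80)), params)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list()
  log <- character()
  for (s in sessions) {
    sid <- s$session_id
    for (stage in stages) {
      res <- tryCatch(
        switch(stage,
          tuning = .stage_tuning(s, seed, p),
          correlations = .stage_correlations(s, seed, p),
          timing = .stage_timing(s, seed, p),
          signals = .stage_signals(s, p)),
        error = function(e) {
          if (!is.null(out_dir)) {
            writeLines(paste("FAILED at stage", stage, "session", sid, ":",
                             conditionMessage(e)),
                       file.path(out_dir, "FAILED"))
          }
          stop("stage '", stage, "' failed on session '", sid, "': ",
               conditionMessage(e), call. = FALSE)
        })
      for (nm in names(res)) {
        key <- paste0(sid, "_", nm)
        bundle[[key]] <- res[[nm]]
        if (!is.null(out_dir)) {
          save_results(res[[nm]], file.path(out_dir, paste0(key, ".csv")),
                       config = p, seed = seed)
        }
      }
      log <- c(log, paste0(sid, ": stage ", stage, " ok (seed ", seed, ")"))
    }
  }
  if (!is.null(out_dir)) writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(bundle)
}

.stage_tuning <- function(s, seed, p) {
  ind <- s$events[s$events$kind == "indentation", , drop = FALSE]
  if (nrow(ind) == 0) return(list())
  forces <- sort(unique(ind$force_mN))
  rows <- lapply(names(s$trains), function(uid) {
    train <- s$trains[[uid]]
    th <- detect_threshold(train, ind, n_boot = p$n_boot,
                           seed = stream_seed(seed, "tuning", uid))
    per_force <- do.call(rbind, lapply(forces, function(f) {
      tr <- ind[ind$force_mN == f, , drop = FALSE]
      m <- attr(window_rates(train, tr), "means")
      data.frame(unit_id = uid, force_mN = f, on_hz = m[["on_hz"]],
                 off_hz = m[["off_hz"]], sustained_hz = m[["sustained_hz"]],
                 baseline_hz = m[["baseline_hz"]],
                 threshold_mN = th$threshold_mN %||% NA_real_)
    }))
    per_force
  })
  list(tuning = do.call(rbind, rows))
}

.stage_correlations <- function(s, seed, p) {
  cp <- population_coupling(s, bin_ms = p$bin_ms, epoch = "evoked",
                            n_shuffles = p$n_shuffles,
                            seed = stream_seed(seed, "corr"))
  ps <- pairwise_synchrony(s, bin_ms = p$bin_ms, epoch = "evoked",
                           max_lag_ms = 0)
  nc <- tryCatch(noise_correlations(s), error = function(e) NULL)
  sc <- tryCatch(signal_correlations(s), error = function(e) NULL)
  pairs <- ps[, c("unit_a", "unit_b", "sync_r")]
  if (!is.null(nc)) pairs$noise_r <- nc$noise_r
  if (!is.null(sc)) pairs$signal_r <- sc$signal_r
  list(coupling = cp, pairs = pairs)
}

.stage_timing <- function(s, seed, p) {
  ind <- s$events[s$events$kind == "indentation", , drop = FALSE]
  rows <- list()
  for (f in intersect(p$latency_forces_mN, unique(ind$force_mN))) {
    on <- ind$onset_s[ind$force_mN == f]
    if (length(on) < 50) next
    for (uid in names(s$trains)) {
      lr <- latency_and_jitter(s$trains[[uid]], on,
                               seed = stream_seed(seed, "timing", uid, f))
      rows[[paste(uid, f)]] <- data.frame(unit_id = uid, force_mN = f,
                                          latency_ms = lr$latency_ms,
                                          jitter_ms = lr$jitter_ms,
                                          n_trials = lr$n_trials,
                                          n_with_spike = lr$n_trials_with_spike)
    }
  }
  if (length(rows) == 0) return(list())
  list(latency = do.call(rbind, rows))
}

.stage_signals <- function(s, p) {
  if (is.null(s$lfp)) return(list())
  sp <- lfp_spectrum(s$lfp$traces, s$lfp$fs_hz, band = p$band_hz)
  list(lfp_psd = data.frame(freq_hz = sp$freq_hz, psd = sp$psd,
                            relative_band_power = sp$relative_band_power))
}
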