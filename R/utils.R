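# Internal helpers: seeded RNG streams, spike binning, epoch windows.

#' Derive a child seed from a base seed and a named stream
#'
#' All stochastic operations in the package draw from named streams so that
#' adding units or trials to a simulation does not perturb the spikes of
#' existing ones, and so that scripts can derive independent reproducible
#' seeds per stage. Keys (strings or numbers) are hashed into
#' \[1, 2^31 - 2\].
#'
#' @param seed base integer seed
#' @param ... stream key components (character or numeric scalars)
#' @return an integer seed
#' @export
stream_seed <- function(seed, ...) {
  ids <- list(...)
  h <- as.double(seed) %% 2147483647
  for (id in ids) {
    v <- if (is.character(id)) {
      u <- utf8ToInt(id)
      sum(u * seq_along(u))
    } else {
      as.double(id)
    }
    h <- (h * 48271 + v * 16807 + 11) %% 2147483647
    h <- (h * 69621 + 7) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' Evaluate an expression under a named RNG stream, restoring state after
#' @keywords internal
#' @noRd
with_stream <- function(seed, ..., expr) {
  withr::with_seed(stream_seed(seed, ...), expr)
}

#' Bin spike times over a set of windows
#'
#' Windows are binned independently (bins never straddle a window boundary);
#' a trailing remainder shorter than one bin is dropped.
#'
#' @param times numeric vector of spike times (s)
#' @param windows two-column matrix or data.frame of window start/end times (s)
#' @param bin_s bin width in seconds
#' @return list with `counts` (integer vector, concatenated over windows),
#'   `segment` (integer window index per bin), `bin_s`, `n_bins`
#' @keywords internal
#' @noRd
bin_over_windows <- function(times, windows, bin_s) {
  windows <- as.matrix(windows)
  nb <- pmax(0L, as.integer(floor((windows[, 2] - windows[, 1]) / bin_s + 1e-9)))
  total <- sum(nb)
  counts <- integer(total)
  segment <- integer(total)
  off <- 0L
  for (w in seq_len(nrow(windows))) {
    if (nb[w] == 0L) next
    lo <- windows[w, 1]
    hi <- lo + nb[w] * bin_s
    sel <- times >= lo & times < hi
    if (any(sel)) {
      idx <- pmin(nb[w], as.integer(floor((times[sel] - lo) / bin_s)) + 1L)
      counts[off + seq_len(nb[w])] <- tabulate(idx, nbins = nb[w])
    }
    segment[off + seq_len(nb[w])] <- w
    off <- off + nb[w]
  }
  list(counts = counts, segment = segment, bin_s = bin_s, n_bins = total)
}

#' Count spikes in half-open interval (lo, hi]
#' @keywords internal
#' @noRd
count_in <- function(times, lo, hi) {
  sum(times > lo & times <= hi)
}

# Response-window conventions for step indentation: ON 0-50 ms after onset,
# OFF 0-50 ms after offset, SUSTAINED the 200 ms before offset.
.win_on_s <- 0.05
.win_off_s <- 0.05
.win_sus_s <- 0.2

#' Windows of an analysis epoch
#'
#' Converts an epoch label into a set of non-overlapping time windows over a
#' session. `evoked` is the union of ON, OFF and sustained windows of every
#' indentation trial (OFF and sustained are contiguous and merged);
#' `spontaneous` uses the leading stimulus-free block when the session has
#' one, otherwise the per-trial pre-stimulus baselines.
#'
#' @param session a `session` object
#' @param epoch one of `"evoked"`, `"full_step"`, `"onset"`, `"offset"`,
#'   `"sustained"`, `"spontaneous"`, `"brush"`
#' @param baseline_s baseline length used for `spontaneous` fallback windows
#' @return two-column matrix of window start/end times (s)
#' @export
epoch_windows <- function(session, epoch = "evoked", baseline_s = 1.5) {
  ev <- session$events
  ind <- ev[ev$kind == "indentation", , drop = FALSE]
  epoch <- match.arg(epoch, c("evoked", "full_step", "onset", "offset",
                              "sustained", "spontaneous", "brush"))
  w <- switch(epoch,
    evoked = rbind(
      cbind(ind$onset_s, ind$onset_s + .win_on_s),
      cbind(ind$offset_s - .win_sus_s, ind$offset_s + .win_off_s)
    ),
    full_step = cbind(ind$onset_s, ind$offset_s),
    onset = cbind(ind$onset_s, ind$onset_s + .win_on_s),
    offset = cbind(ind$offset_s, ind$offset_s + .win_off_s),
    sustained = cbind(ind$offset_s - .win_sus_s, ind$offset_s),
    spontaneous = {
      if (!is.null(session$spont_dur_s) && session$spont_dur_s > 0) {
        cbind(0, session$spont_dur_s)
      } else {
        cbind(ind$onset_s - baseline_s, ind$onset_s)
      }
    },
    brush = {
      br <- ev[ev$kind == "brush", , drop = FALSE]
      cbind(br$onset_s, br$offset_s)
    }
  )
  if (is.null(w) || nrow(w) == 0) stop("epoch '", epoch, "' is empty for this session")
  w <- w[order(w[, 1]), , drop = FALSE]
  colnames(w) <- c("start_s", "end_s")
  w
}

#' Bin every unit of a session over an epoch
#' @return list: `counts` matrix (units x bins), `segment`, `bin_s`
#' @keywords internal
#' @noRd
bin_session <- function(session, windows, bin_s, unit_ids = NULL) {
  trains <- session$trains
  if (!is.null(unit_ids)) trains <- trains[unit_ids]
  mats <- lapply(trains, function(tr) bin_over_windows(tr$spike_times, windows, bin_s))
  counts <- do.call(rbind, lapply(mats, `[[`, "counts"))
  rownames(counts) <- names(trains)
  list(counts = counts, segment = mats[[1]]$segment, bin_s = bin_s)
}

#' Trapezoid integral over a frequency grid
#' @keywords internal
#' @noRd
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
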