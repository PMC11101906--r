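# Session data model: spike trains, unit metadata, stimulus events, and the
# on-disk session directory layout.

#' Construct a spike train
#'
#' @param unit_id character scalar
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   ascending, non-negative, all below `t_stop`. Times closer than the
#'   sampling resolution (50 microseconds at 20 kHz) are treated as
#'   duplicates and rejected.
#' @param t_stop recording duration in seconds
#' @param min_isi_s duplicate-resolution limit (s)
#' @return object of class `spike_train`
#' @export
spike_train <- function(unit_id, spike_times, t_stop, min_isi_s = 50e-6) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 0) {
    if (any(spike_times < 0)) {
      stop("unit ", unit_id, ": negative spike times")
    }
    if (any(spike_times >= t_stop)) {
      stop("unit ", unit_id, ": spike times at or beyond t_stop")
    }
    d <- diff(spike_times)
    if (any(d <= 0)) {
      stop("unit ", unit_id, ": spike times not strictly ascending")
    }
    if (any(d < min_isi_s - 1e-12)) {
      stop("unit ", unit_id, ": duplicate spikes at the sampling resolution")
    }
  }
  structure(list(unit_id = as.character(unit_id),
                 spike_times = spike_times,
                 t_stop = as.numeric(t_stop)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes over %.1f s (%.2f Hz)>\n",
              x$unit_id, length(x$spike_times), x$t_stop,
              length(x$spike_times) / x$t_stop))
  invisible(x)
}

#' Construct a session
#'
#' A session bundles the simultaneously recorded spike trains, their unit
#' metadata (depth below the dorsal surface in micrometers, channel), the
#' stimulus event table, and optional LFP traces. All analysis stages consume
#' sessions, never raw files.
#'
#' @param session_id character scalar
#' @param trains named list of `spike_train` objects
#' @param meta data.frame with columns `unit_id`, `depth_um`, `channel` and
#'   optionally `opto_label`
#' @param events data.frame with columns `kind` (one of `indentation`,
#'   `brush`, `light`), `onset_s`, `offset_s`, `force_mN`, `block`,
#'   `trial_index`
#' @param lfp optional list with `traces` (samples x channels matrix) and
#'   `fs_hz`
#' @param condition free-form group label (e.g. `"sham"`, `"sni"`)
#' @param ground_truth optional generator ground truth (see
#'   [simulate_session()])
#' @param spont_dur_s length of a leading stimulus-free block, if any
#' @param depth_max_um upper bound for valid recording depths
#' @return validated object of class `session`
#' @export
session <- function(session_id, trains, meta, events, lfp = NULL,
                    condition = "unlabeled", ground_truth = NULL,
                    spont_dur_s = 0, depth_max_um = 620) {
  s <- structure(list(session_id = session_id, condition = condition,
                      trains = trains, meta = meta, events = events,
                      lfp = lfp, ground_truth = ground_truth,
                      spont_dur_s = spont_dur_s),
                 class = "session")
  validate_session(s, depth_max_um = depth_max_um)
  s
}

#' Validate session invariants
#'
#' Checks unit/metadata agreement, depth range, event ordering, event times
#' within the recording, non-overlap of events of one kind, and force range
#' for indentation steps. Raises an error naming the offending unit or trial.
#'
#' @param s a `session`
#' @param depth_max_um maximum valid depth
#' @param force_range_mN valid innocuous force range
#' @return the session, invisibly
#' @export
validate_session <- function(s, depth_max_um = 620, force_range_mN = c(1, 75)) {
  if (length(s$trains) < 1) stop("session must contain at least one unit")
  ids <- vapply(s$trains, `[[`, "", "unit_id")
  if (is.null(names(s$trains))) names(s$trains) <- ids
  if (!all(c("unit_id", "depth_um", "channel") %in% names(s$meta))) {
    missing <- setdiff(c("unit_id", "depth_um", "channel"), names(s$meta))
    stop("unit_meta: missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!setequal(ids, s$meta$unit_id)) {
    stop("unit metadata does not match spike trains: ",
         paste(setdiff(union(ids, s$meta$unit_id), intersect(ids, s$meta$unit_id)),
               collapse = ", "))
  }
  bad_depth <- s$meta$unit_id[s$meta$depth_um < 0 | s$meta$depth_um > depth_max_um]
  if (length(bad_depth)) {
    stop("depth_um outside [0, ", depth_max_um, "] for unit(s): ",
         paste(bad_depth, collapse = ", "))
  }
  ev <- s$events
  req <- c("kind", "onset_s", "offset_s", "trial_index")
  if (!all(req %in% names(ev))) {
    stop("events: missing required column(s): ",
         paste(setdiff(req, names(ev)), collapse = ", "))
  }
  bad <- ev$trial_index[ev$offset_s <= ev$onset_s]
  if (length(bad)) {
    stop("events with offset_s <= onset_s at trial_index: ",
         paste(bad, collapse = ", "))
  }
  t_min <- min(vapply(s$trains, `[[`, 0, "t_stop"))
  if (nrow(ev) && (any(ev$onset_s < 0) || any(ev$offset_s > t_min))) {
    stop("event times outside the recording [0, ", t_min, "]")
  }
  ind <- ev[ev$kind == "indentation", , drop = FALSE]
  if (nrow(ind)) {
    f <- ind$force_mN
    if (any(is.na(f)) || any(f < force_range_mN[1]) || any(f > force_range_mN[2])) {
      stop("indentation force_mN outside [", force_range_mN[1], ", ",
           force_range_mN[2], "] mN")
    }
  }
  for (k in unique(ev$kind)) {
    e <- ev[ev$kind == k, , drop = FALSE]
    e <- e[order(e$onset_s), , drop = FALSE]
    if (nrow(e) > 1 && any(e$onset_s[-1] < e$offset_s[-nrow(e)])) {
      stop("overlapping '", k, "' events (trials must not overlap)")
    }
  }
  invisible(s)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s [%s]: %d units, %d events>\n", x$session_id,
              x$condition, length(x$trains), nrow(x$events)))
  invisible(x)
}

#' Depth stratum of each unit
#'
#' Superficial is the half-open interval `[0, boundary_um)`; a unit exactly
#' at the boundary is deep.
#'
#' @param session a `session`
#' @param boundary_um stratum boundary, default 240
#' @return named character vector (`"superficial"`/`"deep"`) per unit
#' @export
unit_strata <- function(session, boundary_um = 240) {
  out <- ifelse(session$meta$depth_um < boundary_um, "superficial", "deep")
  names(out) <- session$meta$unit_id
  out
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session directory
#'
#' Layout: `units/<unit_id>.csv` (column `spike_time_s`), `unit_meta.csv`,
#' `events.csv`, optional `lfp.csv` (one column per channel) with a
#' `lfp_meta.json` sidecar carrying `fs_hz`, and `ground_truth.json` when the
#' session was simulated. Numeric values are written at full double
#' precision so that a load round-trips exactly.
#'
#' @param s a `session`
#' @param path directory to create
#' @return `path`, invisibly
#' @export
save_session <- function(s, path) {
  dir.create(file.path(path, "units"), recursive = TRUE, showWarnings = FALSE)
  for (tr in s$trains) {
    df <- data.frame(spike_time_s = .fmt_num(tr$spike_times))
    utils::write.csv(df, file.path(path, "units", paste0(tr$unit_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- s$meta
  meta$t_stop_s <- .fmt_num(vapply(s$trains[meta$unit_id], `[[`, 0, "t_stop"))
  meta$depth_um <- .fmt_num(meta$depth_um)
  utils::write.csv(meta, file.path(path, "unit_meta.csv"),
                   row.names = FALSE, quote = FALSE)
  ev <- s$events
  for (col in c("onset_s", "offset_s", "force_mN")) {
    if (col %in% names(ev)) ev[[col]] <- ifelse(is.na(ev[[col]]), NA, .fmt_num(ev[[col]]))
  }
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE, quote = FALSE)
  info <- list(session_id = s$session_id, condition = s$condition,
               spont_dur_s = s$spont_dur_s)
  jsonlite::write_json(info, file.path(path, "session.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(s$lfp)) {
    m <- as.data.frame(s$lfp$traces)
    names(m) <- paste0("ch", seq_len(ncol(m)))
    utils::write.csv(m, file.path(path, "lfp.csv"), row.names = FALSE)
    jsonlite::write_json(list(fs_hz = s$lfp$fs_hz), file.path(path, "lfp_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(s$ground_truth)) {
    jsonlite::write_json(s$ground_truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a session directory
#'
#' Reads the layout written by [save_session()] and validates every
#' invariant; any violation raises an error naming the offending unit or
#' trial. Column names can be remapped through `schema`.
#'
#' @param path session directory
#' @param schema named list remapping expected column names, e.g.
#'   `list(spike_time_s = "t", depth_um = "depth")`
#' @return a validated `session`
#' @export
load_session <- function(path, schema = list()) {
  col <- function(nm) schema[[nm]] %||% nm
  meta_path <- file.path(path, "unit_meta.csv")
  if (!file.exists(meta_path)) stop("no unit_meta.csv in ", path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  for (nm in c("unit_id", "depth_um", "channel")) {
    if (!col(nm) %in% names(meta)) stop("unit_meta.csv: missing column '", col(nm), "'")
    names(meta)[names(meta) == col(nm)] <- nm
  }
  meta$unit_id <- as.character(meta$unit_id)
  ev <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  for (nm in c("kind", "onset_s", "offset_s", "trial_index")) {
    if (!col(nm) %in% names(ev)) stop("events.csv: missing column '", col(nm), "'")
    names(ev)[names(ev) == col(nm)] <- nm
  }
  if (!"force_mN" %in% names(ev)) ev$force_mN <- NA_real_
  if (!"block" %in% names(ev)) ev$block <- NA_character_
  trains <- list()
  for (i in seq_len(nrow(meta))) {
    uid <- meta$unit_id[i]
    f <- file.path(path, "units", paste0(uid, ".csv"))
    if (!file.exists(f)) stop("missing spike file for unit ", uid)
    u <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!col("spike_time_s") %in% names(u)) {
      stop("unit ", uid, ": missing column '", col("spike_time_s"), "'")
    }
    t_stop <- if ("t_stop_s" %in% names(meta)) meta$t_stop_s[i] else {
      max(c(0, u[[col("spike_time_s")]])) + 1
    }
    trains[[uid]] <- spike_train(uid, u[[col("spike_time_s")]], t_stop)
  }
  info_path <- file.path(path, "session.json")
  info <- if (file.exists(info_path)) jsonlite::read_json(info_path) else list()
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.csv"))) {
    m <- as.matrix(utils::read.csv(file.path(path, "lfp.csv")))
    lm <- jsonlite::read_json(file.path(path, "lfp_meta.json"))
    lfp <- list(traces = unname(m), fs_hz = lm$fs_hz)
  }
  gt <- NULL
  if (file.exists(file.path(path, "ground_truth.json"))) {
    gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                              simplifyVector = TRUE)
  }
  meta$t_stop_s <- NULL
  session(session_id = info$session_id %||% basename(path),
          condition = info$condition %||% "unlabeled",
          trains = trains, meta = meta, events = ev, lfp = lfp,
          ground_truth = gt, spont_dur_s = info$spont_dur_s %||% 0)
}

#' Import a spike-sorter export
#'
#' Reads the common sorter export layout: parallel integer arrays of
#' per-spike sample indices and cluster labels, plus a label table marking
#' which clusters are single units. Multi-unit clusters are dropped and
#' counted; empty single-unit clusters are kept with zero spikes and
#' flagged.
#'
#' @param path directory containing `spike_samples.txt`, `spike_clusters.txt`
#'   (one integer per line) and `cluster_labels.csv`
#'   (columns `cluster_id,label`, label `"single"` or `"multi"`)
#' @param fs_hz sampling rate used to convert sample indices to seconds
#' @param t_stop_s recording duration; defaults to last spike + 1 s
#' @return list with `trains` (list of `spike_train`), `n_dropped`,
#'   `empty_units` (unit ids kept with zero spikes)
#' @export
import_sorter_export <- function(path, fs_hz, t_stop_s = NULL) {
  samples <- scan(file.path(path, "spike_samples.txt"), what = integer(),
                  quiet = TRUE)
  clusters <- scan(file.path(path, "spike_clusters.txt"), what = integer(),
                   quiet = TRUE)
  if (length(samples) != length(clusters)) {
    stop("import error: spike_samples (", length(samples),
         ") and spike_clusters (", length(clusters), ") lengths differ")
  }
  labels <- utils::read.csv(file.path(path, "cluster_labels.csv"),
                            stringsAsFactors = FALSE)
  t_stop_s <- t_stop_s %||% (max(c(0, samples)) / fs_hz + 1)
  singles <- labels$cluster_id[labels$label == "single"]
  n_dropped <- sum(labels$label != "single")
  trains <- list()
  empty_units <- character()
  for (cid in singles) {
    uid <- paste0("unit_", cid)
    st <- sort(samples[clusters == cid]) / fs_hz
    if (length(st) == 0) empty_units <- c(empty_units, uid)
    trains[[uid]] <- spike_train(uid, st, t_stop_s)
  }
  list(trains = trains, n_dropped = n_dropped, empty_units = empty_units)
}

#' Write a tidy result table with a JSON sidecar
#'
#' One row per unit or pair; the sidecar records the configuration, seed and
#' package version so a run can be reproduced.
#'
#' @param results data.frame (or list of rows coercible to one)
#' @param path output `.csv` file
#' @param config list serialized into the sidecar
#' @param seed seed recorded in the sidecar
#' @return `path`, invisibly
#' @export
save_results <- function(results, path, config = list(), seed = NULL) {
  if (!is.data.frame(results)) results <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(results) || nrow(results) == 0) {
    warning("empty result list: writing header-only table to ", path)
    if (is.null(results)) results <- data.frame()
  }
  num <- vapply(results, is.numeric, TRUE)
  out <- results
  out[num] <- lapply(out[num], .fmt_num)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(config = config, seed = seed,
                  package = "spikesync",
                  version = as.character(utils::packageVersion("spikesync")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
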