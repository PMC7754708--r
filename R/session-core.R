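## Session container, domain types, and trial bookkeeping.

#' Virtual linear-track geometry
#'
#' The 200-cm track with the start zone, reward zone, stimulation trigger
#' point, and the stimulation summary zone. The reward zone is where the
#' animal must dwell 3 s and lick 3 times for reward; crossing the
#' stimulation point during the stimulation epoch triggers the
#' photostimulation bout.
#'
#' @param track_length track length in cm.
#' @param start_zone,reward_zone `c(lo, hi)` in cm.
#' @param stim_point stimulation trigger position, cm.
#' @param stim_zone summary window after the trigger point, cm (defaults to
#'   the 21.21-cm window after the trigger used for spatial summaries).
#' @param overshoot_pos position treated as "ran into the back wall", cm.
#' @return object of class `track_geometry`.
#' @export
track_geometry <- function(track_length = 200,
                           start_zone = c(21.4, 48.8),
                           reward_zone = c(160, 178.6),
                           stim_point = 105,
                           stim_zone = c(105, 126.21),
                           overshoot_pos = track_length) {
  stopifnot(length(start_zone) == 2, length(reward_zone) == 2,
            start_zone[1] < start_zone[2], reward_zone[1] < reward_zone[2],
            start_zone[2] <= track_length, reward_zone[2] <= track_length,
            stim_point > 0, stim_point < track_length)
  structure(list(track_length = track_length, start_zone = start_zone,
                 reward_zone = reward_zone, stim_point = stim_point,
                 stim_zone = stim_zone, overshoot_pos = overshoot_pos),
            class = "track_geometry")
}

#' Read track-geometry overrides from a JSON sidecar
#'
#' @param path JSON file whose top-level keys override [track_geometry()]
#'   arguments.
#' @export
geometry_from_json <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  ov <- ov[names(ov) %in% names(formals(track_geometry))]
  do.call(track_geometry, ov)
}

#' Session epochs
#'
#' Named, ordered, non-overlapping intervals in session time. A standard
#' session is 15 min baseline, 5 min pre, 10 min stimulation, 5 min post,
#' laid out contiguously.
#'
#' @param durations named numeric vector of epoch durations, seconds, in
#'   session order.
#' @param start start time of the first epoch, seconds.
#' @return data.frame with columns `name`, `start`, `end`; class `epoch_set`.
#' @export
epoch_set <- function(durations = c(baseline = 900, pre = 300,
                                    stim = 600, post = 300),
                      start = 0) {
  stopifnot(!is.null(names(durations)), all(durations > 0))
  e <- data.frame(name = names(durations),
                  start = start + cumsum(c(0, durations[-length(durations)])),
                  end = start + cumsum(durations),
                  stringsAsFactors = FALSE)
  rownames(e) <- NULL
  class(e) <- c("epoch_set", "data.frame")
  e
}

#' Epoch membership of time points
#' @param time times in seconds.
#' @param epochs an `epoch_set`.
#' @return character vector of epoch names (`NA` outside all epochs).
#' @export
epoch_of <- function(time, epochs) {
  out <- rep(NA_character_, length(time))
  for (i in seq_len(nrow(epochs)))
    out[time >= epochs$start[i] & time < epochs$end[i]] <- epochs$name[i]
  out
}

#' Interval of a named epoch
#' @rdname epoch_of
#' @param name epoch name.
#' @export
epoch_interval <- function(epochs, name) {
  i <- match(name, epochs$name)
  if (is.na(i)) stop("unknown epoch: ", name)
  c(epochs$start[i], epochs$end[i])
}

#' Behaviour timeseries
#'
#' 100-Hz behavioural record: position and speed on the track, lick and
#' reward event flags, the trial id of each sample (-1 during inter-trial
#' intervals) and whether the animal is in the virtual world.
#'
#' @param time seconds, uniform grid.
#' @param position cm on `[0, track_length]`.
#' @param speed cm/s.
#' @param lick,reward logical event flags per sample.
#' @param trial_id integer per sample, -1 = inter-trial interval.
#' @param in_world logical per sample.
#' @param sample_rate Hz.
#' @return data.frame of class `behavior_ts`.
#' @export
behavior_timeseries <- function(time, position, speed, lick, reward,
                                trial_id, in_world, sample_rate = 100) {
  n <- length(time)
  lens <- c(length(position), length(speed), length(lick), length(reward),
            length(trial_id), length(in_world))
  if (any(lens != n))
    stop("behavior validation: array lengths differ from time (", n, "): ",
         paste(lens, collapse = ", "))
  dt <- diff(time)
  if (n > 1 && (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-6))
    stop("behavior validation: time must increase with constant step 1/",
         sample_rate, " s")
  if (any(in_world & (position < 0 | position > 1e6)))
    stop("behavior validation: position out of range while in world")
  b <- data.frame(time = time, position = position, speed = speed,
                  lick = as.logical(lick), reward = as.logical(reward),
                  trial_id = as.integer(trial_id),
                  in_world = as.logical(in_world))
  attr(b, "sample_rate") <- sample_rate
  class(b) <- c("behavior_ts", "data.frame")
  b
}

#' Fluorescence trace matrix
#'
#' @param F neurons x frames raw fluorescence matrix, arbitrary units >= 0.
#' @param frame_rate Hz.
#' @param frame_time seconds per frame (defaults to a uniform grid).
#' @param roi_centroids neurons x 2 matrix of ROI centroids, pixels of a
#'   512 x 512 field of view.
#' @param artifact_mask logical per frame, `TRUE` where the frame is
#'   contaminated by stimulation light.
#' @param f0 optional per-neuron resting fluorescence used by the simulator.
#' @return list of class `trace_matrix`.
#' @export
trace_matrix <- function(F, frame_rate = 30, frame_time = NULL,
                         roi_centroids = NULL, artifact_mask = NULL,
                         f0 = NULL) {
  stopifnot(is.matrix(F))
  if (!all(is.finite(F))) {
    bad <- which(!is.finite(F), arr.ind = TRUE)[1, ]
    stop("trace validation: non-finite fluorescence at neuron ", bad[1],
         ", frame ", bad[2])
  }
  nf <- ncol(F)
  frame_time <- frame_time %||% ((seq_len(nf) - 1) / frame_rate)
  if (length(frame_time) != nf || is.unsorted(frame_time, strictly = TRUE))
    stop("trace validation: frame_time must be strictly increasing, one per frame")
  artifact_mask <- artifact_mask %||% rep(FALSE, nf)
  stopifnot(length(artifact_mask) == nf)
  if (!is.null(roi_centroids)) {
    stopifnot(is.matrix(roi_centroids), nrow(roi_centroids) == nrow(F),
              ncol(roi_centroids) == 2)
    if (any(roi_centroids < 0 | roi_centroids >= 512))
      stop("trace validation: ROI centroids must lie within [0, 512) pixels")
  }
  structure(list(F = F, frame_rate = frame_rate, frame_time = frame_time,
                 roi_centroids = roi_centroids,
                 artifact_mask = as.logical(artifact_mask), f0 = f0),
            class = "trace_matrix")
}

#' Photostimulation protocol
#'
#' Five target clusters are illuminated sequentially (100 ms each, 5 ms
#' gaps for SLM/galvo switching) and the cycle is run twice: 1000 ms of
#' light over a 1045-ms bout, triggered each time the animal crosses the
#' stimulation point during the stimulation epoch.
#'
#' @param target_ids neuron indices of the targeted cells.
#' @param cluster_assignment integer 0-4 per target.
#' @param trial_onsets frame indices (1-based) of bout starts.
#' @param beamlet_xy targets x 2 matrix of beamlet coordinates, micrometres.
#' @param n_clusters,cluster_on_ms,gap_ms,n_cycles schedule parameters.
#' @return list of class `stim_protocol`; `$schedule` is a data.frame of the
#'   10 illumination intervals (ms from bout onset) ordered in time.
#' @export
stim_protocol <- function(target_ids = integer(), cluster_assignment = integer(),
                          trial_onsets = integer(), beamlet_xy = NULL,
                          n_clusters = 5, cluster_on_ms = 100, gap_ms = 5,
                          n_cycles = 2) {
  stopifnot(length(cluster_assignment) == length(target_ids))
  if (length(cluster_assignment) && (min(cluster_assignment) < 0 ||
                                     max(cluster_assignment) >= n_clusters))
    stop("protocol validation: cluster_assignment must lie in 0..", n_clusters - 1)
  slot <- cluster_on_ms + gap_ms
  j <- seq_len(n_clusters * n_cycles) - 1
  schedule <- data.frame(
    illum = j,
    cluster = j %% n_clusters,
    cycle = j %/% n_clusters,
    on_ms = j * slot,
    off_ms = j * slot + cluster_on_ms)
  bout_ms <- n_clusters * n_cycles * slot - gap_ms
  structure(list(target_ids = as.integer(target_ids),
                 cluster_assignment = as.integer(cluster_assignment),
                 trial_onsets = as.integer(trial_onsets),
                 beamlet_xy = beamlet_xy, schedule = schedule,
                 n_clusters = n_clusters, cluster_on_ms = cluster_on_ms,
                 gap_ms = gap_ms, n_cycles = n_cycles, bout_ms = bout_ms),
            class = "stim_protocol")
}

#' Assemble a session container
#'
#' @param behavior a [behavior_timeseries()].
#' @param traces a [trace_matrix()].
#' @param epochs an [epoch_set()].
#' @param geometry a [track_geometry()].
#' @param protocol a [stim_protocol()] or `NULL` for no-stimulation sessions.
#' @param trials optional trial table (built on demand otherwise).
#' @param meta named list (e.g. `session_type`).
#' @return list of class `session_data`.
#' @export
session_data <- function(behavior, traces, epochs, geometry,
                         protocol = NULL, trials = NULL, meta = list()) {
  s <- structure(list(behavior = behavior, traces = traces, epochs = epochs,
                      geometry = geometry, protocol = protocol,
                      trials = trials, meta = meta),
                 class = "session_data")
  validate_session(s)
  s
}

#' Validate a session container against the schema
#'
#' Checks presence of required groups, cross-array lengths, finiteness of
#' the trace matrix and positional bounds. Called by [load_session()].
#'
#' @param s a `session_data` list.
#' @return `s`, invisibly; errors name the offending path.
#' @export
validate_session <- function(s) {
  req <- c("behavior", "traces", "epochs", "geometry")
  miss <- setdiff(req, names(s)[!vapply(s, is.null, TRUE)])
  if (length(miss))
    stop("session schema: missing group(s): /", paste(miss, collapse = ", /"))
  b <- s$behavior
  for (col in c("time", "position", "speed", "lick", "reward", "trial_id",
                "in_world"))
    if (is.null(b[[col]]))
      stop("session schema: missing dataset /behavior/", col)
  if (!all(is.finite(s$traces$F))) {
    bad <- which(!is.finite(s$traces$F), arr.ind = TRUE)[1, ]
    stop("session validation: non-finite value in /traces/F at neuron ",
         bad[1], ", frame ", bad[2])
  }
  if (length(s$traces$artifact_mask) != ncol(s$traces$F))
    stop("session validation: /traces/artifact_mask length ",
         length(s$traces$artifact_mask), " != n frames ", ncol(s$traces$F))
  if (is.null(s$protocol)) {
    ty <- s$meta$session_type %||% "no_stim"
    if (!identical(ty, "no_stim"))
      stop("session schema: missing group /protocol for session_type '", ty, "'")
  }
  invisible(s)
}

#' Save / load a session container
#'
#' One self-contained file per session holding the behaviour timeseries,
#' trace matrix, epochs, geometry, protocol and metadata (serialised R
#' objects; logical layout behavior/traces/protocol/epochs/meta). Loading
#' re-validates the schema; a session typed `no_stim` may omit the protocol,
#' which loads as an empty [stim_protocol()].
#'
#' @param session a `session_data`.
#' @param path file path.
#' @export
save_session <- function(session, path) {
  saveRDS(unclass_deep(session), path)
  invisible(path)
}

unclass_deep <- function(x) x  # containers are stored as-is

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("session container not found: ", path)
  s <- readRDS(path)
  if (!inherits(s, "session_data")) class(s) <- "session_data"
  validate_session(s)
  if (is.null(s$protocol)) s$protocol <- stim_protocol()
  s
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data> ", nrow(x$traces$F), " neurons x ", ncol(x$traces$F),
      " frames; ", nrow(x$epochs), " epochs; ",
      if (length(x$protocol$target_ids)) paste0(length(x$protocol$target_ids),
        " targets, ", length(x$protocol$trial_onsets), " stim trials")
      else "no stimulation", "\n", sep = "")
  invisible(x)
}

#' Build the trial table from behaviour
#'
#' One record per contiguous in-world trial segment. Outcomes follow the
#' task rules: a reward flag makes the trial `correct`; more than 10 licks
#' outside the reward zone make it `fail_lick`; otherwise a trial that ended
#' at the back wall is `fail_overshoot`. A truncated segment matching no
#' rule gets outcome `NA` with `complete = FALSE`.
#'
#' @param behavior a [behavior_timeseries()].
#' @param geometry a [track_geometry()].
#' @return data.frame with one row per trial: times, outcome,
#'   `reached_stim_point`, `max_position`, lick counts in/out of the reward
#'   zone.
#' @export
build_trial_table <- function(behavior, geometry = track_geometry()) {
  tid <- behavior$trial_id
  seg <- rle(tid)
  ends <- cumsum(seg$lengths)
  starts <- ends - seg$lengths + 1
  keep <- seg$values >= 0
  ids <- seg$values[keep]
  if (anyDuplicated(ids))
    stop("trial structure: trial_id ", ids[duplicated(ids)][1],
         " appears in non-contiguous segments")
  starts <- starts[keep]; ends <- ends[keep]
  rz <- geometry$reward_zone
  recs <- lapply(seq_along(ids), function(k) {
    i <- starts[k]:ends[k]
    pos <- behavior$position[i]
    lick <- behavior$lick[i]
    in_zone <- pos >= rz[1] & pos <= rz[2]
    n_in <- sum(lick & in_zone)
    n_out <- sum(lick & !in_zone)
    rewarded <- any(behavior$reward[i])
    maxp <- max(pos)
    outcome <- if (rewarded) "correct"
      else if (n_out > 10) "fail_lick"
      else if (maxp >= geometry$overshoot_pos - 1e-9) "fail_overshoot"
      else NA_character_
    data.frame(trial_id = ids[k],
               start_time = behavior$time[i[1]],
               end_time = behavior$time[i[length(i)]],
               outcome = outcome,
               complete = !is.na(outcome),
               reached_stim_point = maxp >= geometry$stim_point,
               max_position = maxp,
               n_licks_in_zone = n_in,
               n_licks_out_zone = n_out,
               stringsAsFactors = FALSE)
  })
  tt <- do.call(rbind, recs)
  if (is.null(tt)) tt <- data.frame(trial_id = integer(), start_time = numeric(),
    end_time = numeric(), outcome = character(), complete = logical(),
    reached_stim_point = logical(), max_position = numeric(),
    n_licks_in_zone = integer(), n_licks_out_zone = integer())
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Trials whose start falls inside a named epoch
#' @param trials a trial table.
#' @param epochs an `epoch_set`.
#' @param name epoch name.
#' @export
epoch_trials <- function(trials, epochs, name) {
  iv <- epoch_interval(epochs, name)
  trials[trials$start_time >= iv[1] & trials$start_time < iv[2], , drop = FALSE]
}

#' Export a trial table to CSV
#' @param trials trial table.
#' @param path output file.
#' @export
export_trial_table <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
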