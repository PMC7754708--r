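## Raw fluorescence -> dF/F, running-speed filtering, spatial tuning maps,
## event rates, and ROI matching across epochs.

#' Sliding-percentile dF/F
#'
#' Removes slow drift in baseline fluorescence by normalising each frame by
#' a low percentile (default the 8th) of the raw trace in a window (default
#' 10 s) centred on that frame and truncated at the recording edges:
#' `dF/F = (F - F0) / F0` with `F0` the windowed percentile.
#'
#' @param traces a [trace_matrix()], or a bare neurons x frames matrix.
#' @param window_s window length in seconds.
#' @param percentile baseline percentile (0-100).
#' @param frame_rate frames per second (taken from `traces` when available).
#' @return neurons x frames matrix of dF/F fractions.
#' @export
compute_dff <- function(traces, window_s = 10, percentile = 8,
                        frame_rate = NULL) {
  F <- if (inherits(traces, "trace_matrix")) traces$F else traces
  frame_rate <- frame_rate %||%
    (if (inherits(traces, "trace_matrix")) traces$frame_rate else 30)
  halfwin <- round(window_s * frame_rate / 2)
  if (halfwin < 1) stop("dF/F window must span at least one frame")
  F0 <- sliding_percentile(F, as.integer(halfwin), percentile / 100)
  if (any(F0 <= 0)) {
    bad <- which(F0 <= 0, arr.ind = TRUE)[1, ]
    stop("dF/F baseline non-positive at neuron ", bad[1], ", frame ", bad[2])
  }
  (F - F0) / F0
}

#' Frame-aligned running mask
#'
#' `TRUE` for imaging frames where the animal is in the virtual world and
#' running strictly faster than the threshold (default 5 cm/s).
#'
#' @param behavior a [behavior_timeseries()].
#' @param frame_time imaging frame times, seconds.
#' @param threshold speed threshold, cm/s (strict inequality).
#' @return logical vector, one element per frame.
#' @export
velocity_mask <- function(behavior, frame_time, threshold = 5) {
  skew <- max(frame_time[1] - behavior$time[1],
              max(frame_time) - max(behavior$time), 0)
  if (skew > 1 / 15)
    stop("alignment error: imaging clock extends ", round(skew, 3),
         " s beyond the behaviour record")
  fb <- behavior_at_frames(behavior, frame_time)
  fb$in_world & fb$speed > threshold
}

#' Spatially binned tuning maps
#'
#' For each trial, the mean dF/F of velocity-filtered frames per spatial
#' bin (default 2.27 cm), Gaussian-smoothed along bins (default SD 3 bins,
#' kernel truncated and renormalised at the track ends). Bins with no
#' filtered occupancy are `NA`, never zero-filled; the trial average
#' ignores them.
#'
#' @param dff neurons x frames dF/F matrix.
#' @param frame_behavior frame-aligned behaviour from an internal
#'   interpolation of the 100-Hz record (see [velocity_mask()]), i.e. a
#'   data.frame with `position` and `trial_id` per frame.
#' @param mask logical per frame (running filter); frames with `FALSE` are
#'   ignored.
#' @param geometry a [track_geometry()].
#' @param trial_ids trials to include (default: all trials present).
#' @param bin_width bin width, cm.
#' @param sd_bins smoothing SD in bins (0 = no smoothing).
#' @return object of class `place_map`: list with `per_trial`
#'   (neurons x trials x bins), `trial_avg` (neurons x bins), `trial_ids`,
#'   `bin_width`, `bin_centers`, `smoothing_sd_bins`.
#' @export
spatial_tuning_map <- function(dff, frame_behavior, mask, geometry,
                               trial_ids = NULL, bin_width = 2.27,
                               sd_bins = 3) {
  nb <- n_bins(bin_width, geometry$track_length)
  trial_ids <- trial_ids %||%
    sort(unique(frame_behavior$trial_id[frame_behavior$trial_id >= 0]))
  nn <- nrow(dff)
  per_trial <- array(NA_real_, dim = c(nn, length(trial_ids), nb))
  drop_tr <- logical(length(trial_ids))
  for (k in seq_along(trial_ids)) {
    sel <- which(frame_behavior$trial_id == trial_ids[k] & mask)
    if (!length(sel)) { drop_tr[k] <- TRUE; next }
    b <- position_bin(frame_behavior$position[sel], bin_width,
                      geometry$track_length)
    cnt <- tabulate(b, nb)
    sums <- rowsum_by_bin(dff[, sel, drop = FALSE], b, nb)
    m <- sweep(sums, 2, cnt, "/")
    m[, cnt == 0] <- NA_real_
    per_trial[, k, ] <- smooth_bins(m, sd_bins)
  }
  if (any(drop_tr)) {
    warning("excluding ", sum(drop_tr), " trial(s) with zero filtered occupancy")
    per_trial <- per_trial[, !drop_tr, , drop = FALSE]
    trial_ids <- trial_ids[!drop_tr]
  }
  trial_avg <- apply(per_trial, c(1, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(per_trial = per_trial, trial_avg = trial_avg,
                 trial_ids = trial_ids, bin_width = bin_width,
                 n_bins = nb,
                 bin_centers = bin_centers(bin_width, geometry$track_length),
                 smoothing_sd_bins = sd_bins),
            class = "place_map")
}

rowsum_by_bin <- function(m, bins, nb) {
  out <- matrix(0, nrow(m), nb)
  agg <- rowsum(t(m), group = bins)  # rows named by sorted unique bin
  out[, as.integer(rownames(agg))] <- t(agg)
  out
}

#' Calcium event rate
#'
#' Counts upward crossings of mean + `threshold_sd` standard deviations of
#' the dF/F trace within the masked samples (statistics computed on that
#' same masked epoch) and divides by the masked duration.
#'
#' @param dff numeric vector or neurons x frames matrix.
#' @param mask logical per frame; must select at least one second of data.
#' @param threshold_sd threshold in SDs above the mean.
#' @param frame_rate frames per second.
#' @return events per second (vector, one per neuron).
#' @export
event_rate <- function(dff, mask = NULL, threshold_sd = 3, frame_rate = 30) {
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1)
  mask <- mask %||% rep(TRUE, ncol(dff))
  if (sum(mask) < frame_rate)
    stop("event_rate: mask selects less than one second of data")
  x <- dff[, mask, drop = FALSE]
  dur <- ncol(x) / frame_rate
  apply(x, 1, function(v) {
    s <- sd(v)
    if (s == 0 || !is.finite(s)) {
      warning("zero-variance trace; event rate 0")
      return(0)
    }
    thr <- mean(v) + threshold_sd * s
    above <- v > thr
    sum(above & !c(FALSE, above[-length(above)])) / dur
  })
}

#' Match ROI centroids across epochs
#'
#' Greedy nearest-neighbour one-to-one pairing of two centroid lists;
#' pairs farther apart than the tolerance (default 4 pixels) are left
#' unmatched. Used as the session stability filter: cells are kept only if
#' they have a corresponding ROI throughout the recordings.
#'
#' @param centroids_a,centroids_b n x 2 centroid matrices (pixels).
#' @param tol_px matching tolerance in pixels.
#' @return data.frame with columns `a`, `b`, `dist` (one row per pair).
#' @export
match_rois <- function(centroids_a, centroids_b, tol_px = 4) {
  na <- nrow(centroids_a); nb2 <- nrow(centroids_b)
  if (na == 0 || nb2 == 0)
    return(data.frame(a = integer(), b = integer(), dist = numeric()))
  d <- sqrt(outer(centroids_a[, 1], centroids_b[, 1], "-")^2 +
            outer(centroids_a[, 2], centroids_b[, 2], "-")^2)
  pairs <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || !is.finite(d[m]) || d[m] > tol_px) break
    i <- (m - 1) %% na + 1
    j <- (m - 1) %/% na + 1
    pairs[[length(pairs) + 1]] <- data.frame(a = i, b = j, dist = d[m])
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(a = integer(), b = integer(), dist = numeric())
  out[order(out$a), , drop = FALSE]
}

#' Export a place map to CSV (one row per neuron x trial)
#' @param map a `place_map`.
#' @param path output file.
#' @export
export_place_map <- function(map, path) {
  d <- dim(map$per_trial)
  rows <- expand.grid(neuron = seq_len(d[1]), trial = map$trial_ids)
  vals <- matrix(aperm(map$per_trial, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(vals) <- sprintf("bin_%03d", seq_len(d[3]))
  write.csv(cbind(rows, vals), path, row.names = FALSE)
  invisible(path)
}
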