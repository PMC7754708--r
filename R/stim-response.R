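## Photostimulation response calling: peri-stimulus extraction, the 10
## post-cluster response windows, responsive-cell classification, off-target
## screening, response stability, and the stimulation-efficacy score.

#' Extract peri-stimulus traces
#'
#' For each stimulation trial the raw fluorescence trace is extracted for
#' 30 frames before and 120 frames after the bout onset and normalised by
#' subtracting and dividing by that trial's mean baseline over frames 5-29
#' of the extracted trace (0-based; all pre-onset). Onsets too close to a
#' recording edge are dropped with a warning. The trace matrix's artifact
#' mask is carried alongside so window statistics can exclude uncorrected
#' frames.
#'
#' @param traces a [trace_matrix()] (raw fluorescence).
#' @param onsets bout onset frame indices (1-based).
#' @param pre,post frames kept before / after onset.
#' @return object of class `peristim_tensor`: list with `x` (neurons x
#'   trials x frames), `artifact` (trials x frames), `rel_frames`
#'   (-pre..post-1), `onsets`.
#' @export
extract_peristim <- function(traces, onsets, pre = 30, post = 120) {
  F <- traces$F
  nf <- ncol(F)
  ok <- onsets - pre >= 1 & onsets + post - 1 <= nf
  if (any(!ok))
    warning("dropping ", sum(!ok), " onset(s) too close to the recording edge")
  onsets <- onsets[ok]
  if (!length(onsets)) stop("no usable stimulation trials")
  nn <- nrow(F); ntr <- length(onsets); nw <- pre + post
  x <- array(NA_real_, c(nn, ntr, nw))
  art <- matrix(FALSE, ntr, nw)
  for (k in seq_len(ntr)) {
    idx <- (onsets[k] - pre):(onsets[k] + post - 1)
    seg <- F[, idx, drop = FALSE]
    b <- rowMeans(seg[, 6:30, drop = FALSE])  # frames 5-29, 0-based
    x[, k, ] <- (seg - b) / b
    art[k, ] <- traces$artifact_mask[idx]
  }
  structure(list(x = x, artifact = art, rel_frames = seq_len(nw) - pre - 1,
                 onsets = onsets, pre = pre, post = post),
            class = "peristim_tensor")
}

#' The 10 post-cluster response windows
#'
#' Each of the 10 cluster illuminations (5 clusters x 2 cycles) is followed
#' by a ~100-ms (3-frame at 30 Hz) response window beginning at the frame
#' in which that illumination completes, ordered in time.
#'
#' @param protocol a [stim_protocol()].
#' @param frame_rate imaging frame rate, Hz.
#' @param width_frames window width in frames.
#' @return data.frame with `window` (0-9), `cluster`, `cycle`, `from`, `to`
#'   (frames after bout onset, 0-based).
#' @export
response_windows <- function(protocol, frame_rate = 30, width_frames = 3) {
  sch <- protocol$schedule
  if (nrow(sch) != 10)
    stop("protocol error: schedule must contain 10 cluster illuminations")
  from <- ceiling(sch$off_ms / 1000 * frame_rate)
  data.frame(window = sch$illum, cluster = sch$cluster, cycle = sch$cycle,
             from = from, to = from + width_frames - 1)
}

# per-neuron x per-trial mean dF/F in one window (optionally excluding
# artifact-flagged frames, for traces not artifact-corrected)
window_amplitude <- function(tensor, from, to, exclude_artifact = FALSE) {
  sel <- which(tensor$rel_frames >= from & tensor$rel_frames <= to)
  nn <- dim(tensor$x)[1]; ntr <- dim(tensor$x)[2]
  amp <- matrix(NA_real_, nn, ntr)
  for (k in seq_len(ntr)) {
    use <- sel
    if (exclude_artifact) use <- sel[!tensor$artifact[k, sel]]
    if (!length(use)) next
    amp[, k] <- rowMeans(tensor$x[, k, use, drop = FALSE], dims = 1)
  }
  amp
}

#' Preferred stimulation window per neuron
#'
#' Argmax over the 10 windows of the trial-averaged window-mean dF/F; ties
#' resolved to the earliest window.
#'
#' @param tensor a [extract_peristim()] tensor.
#' @param windows data.frame from [response_windows()].
#' @param exclude_artifact drop artifact-flagged frames from window means.
#' @return integer vector of window indices (0-9); `NA` when every window
#'   is artifact-masked.
#' @export
preferred_window <- function(tensor, windows, exclude_artifact = FALSE) {
  nn <- dim(tensor$x)[1]
  means <- sapply(seq_len(nrow(windows)), function(w) {
    amp <- window_amplitude(tensor, windows$from[w], windows$to[w],
                            exclude_artifact)
    rowMeans(amp, na.rm = TRUE)
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = nn)
  apply(means, 1, function(v) {
    if (all(is.nan(v) | is.na(v))) return(NA_integer_)
    windows$window[which.max(v)]
  })
}

#' Classify photostimulation-responsive neurons
#'
#' A neuron is responsive iff its dF/F exceeds `amp` (default 0.40) on
#' strictly more than `frac` (default 30%) of trials in its preferred
#' stimulation window; both inequalities are strict.
#'
#' @param tensor a peristim tensor (>= 5 stimulation trials recommended).
#' @param windows data.frame from [response_windows()].
#' @param amp,frac response thresholds.
#' @param is_target logical per neuron.
#' @param cluster integer per neuron (NA for non-targets).
#' @param exclude_artifact see [preferred_window()].
#' @return data.frame of class `response_table`: `neuron_id`,
#'   `preferred_window`, `responsive`, `mean_amplitude`, `hit_fraction`,
#'   `is_target`, `cluster`; per-trial amplitudes in attribute
#'   `"trial_amplitudes"` (neurons x trials).
#' @export
classify_responsive <- function(tensor, windows, amp = 0.40, frac = 0.30,
                                is_target = NULL, cluster = NULL,
                                exclude_artifact = FALSE) {
  nn <- dim(tensor$x)[1]; ntr <- dim(tensor$x)[2]
  pw <- preferred_window(tensor, windows, exclude_artifact)
  ta <- matrix(NA_real_, nn, ntr)
  for (w in unique(pw[!is.na(pw)])) {
    rows <- which(pw == w)
    wi <- which(windows$window == w)
    a <- window_amplitude(tensor, windows$from[wi], windows$to[wi],
                          exclude_artifact)
    ta[rows, ] <- a[rows, ]
  }
  hit <- rowMeans(ta > amp, na.rm = TRUE)
  hit[is.na(pw)] <- NA
  res <- data.frame(neuron_id = seq_len(nn), preferred_window = pw,
                    responsive = !is.na(hit) & hit > frac,
                    mean_amplitude = rowMeans(ta, na.rm = TRUE),
                    hit_fraction = hit,
                    is_target = is_target %||% rep(NA, nn),
                    cluster = cluster %||% rep(NA_integer_, nn))
  attr(res, "trial_amplitudes") <- ta
  class(res) <- c("response_table", "data.frame")
  res
}

#' Screen for off-target responders
#'
#' Off-target responders are non-targeted cells that pass the response
#' criterion during stimulation, do not pass it during no-stimulation
#' epochs (guarding against tuned endogenous activity and remapping), and
#' lie within `radius_um` (default the conservative 30 um) of a laser
#' beamlet.
#'
#' @param records response table from the stimulation epoch.
#' @param no_stim_records response table from a no-stimulation epoch
#'   aligned to the same neurons (or `NULL` if unavailable).
#' @param beamlet_xy targets x 2 beamlet coordinates, micrometres.
#' @param roi_centroids_px neurons x 2 ROI centroids, pixels.
#' @param radius_um proximity limit, micrometres.
#' @param um_per_px field-of-view calibration (800 um / 512 px).
#' @return integer vector of off-target responder neuron ids.
#' @export
detect_off_target <- function(records, no_stim_records, beamlet_xy,
                              roi_centroids_px, radius_um = 30,
                              um_per_px = 800 / 512) {
  if (is.null(um_per_px) || !is.finite(um_per_px))
    stop("missing micrometres-per-pixel calibration")
  cand <- which(records$responsive & !(records$is_target %in% TRUE))
  if (!is.null(no_stim_records))
    cand <- setdiff(cand, which(no_stim_records$responsive))
  if (!length(cand) || is.null(beamlet_xy) || !nrow(beamlet_xy))
    return(integer(0))
  xy <- roi_centroids_px[cand, , drop = FALSE] * um_per_px
  dmin <- apply(xy, 1, function(p)
    min(sqrt((beamlet_xy[, 1] - p[1])^2 + (beamlet_xy[, 2] - p[2])^2)))
  cand[dmin <= radius_um]
}

#' Response stability over stimulation trials
#'
#' Ordinary least-squares slope of the responding target population's mean
#' amplitude against trial index; compared to zero at the cohort level in
#' reports.
#'
#' @param trial_amplitudes responsive-target amplitudes (neurons x trials)
#'   or a population-mean vector per trial.
#' @return list `slope`, `intercept`, `n_trials`.
#' @export
response_stability_slope <- function(trial_amplitudes) {
  y <- if (is.null(dim(trial_amplitudes))) trial_amplitudes
    else colMeans(trial_amplitudes, na.rm = TRUE)
  x <- seq_along(y)
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_trials = length(y))
}

#' Stimulation efficacy score
#'
#' Specificity = (responding Reward-PCs - responding Start-PCs) / total
#' responding neurons; efficacy = specificity x total responding x mean
#' response amplitude, i.e. (nReward - nStart) x mean amplitude. Positive
#' values mean reward-zone-specific stimulation.
#'
#' @param n_reward,n_start,n_total responsive counts.
#' @param mean_amplitude mean response dF/F of responsive neurons.
#' @return list `specificity`, `efficacy` (`NA` when `n_total` is 0).
#' @export
stimulation_efficacy <- function(n_reward, n_start, n_total, mean_amplitude) {
  if (n_total <= 0) return(list(specificity = NA_real_, efficacy = NA_real_))
  spec <- (n_reward - n_start) / n_total
  list(specificity = spec, efficacy = spec * n_total * mean_amplitude)
}
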