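## Spatial behavioural maps (lick rate, speed, occupancy, deceleration
## events), epoch deltas, windowed summaries, outcome deltas against control
## sessions, and the deceleration-peak progression with its block-order
## permutation null.

#' Spatially binned behavioural map
#'
#' Per trial, the chosen variable across 3.03-cm track bins: `occupancy`
#' (seconds in bin), `lick_rate` (licks per second of occupancy), `speed`
#' (occupancy-weighted mean, cm/s) or `decel_events` (deceleration-event
#' counts; see [deceleration_events()]). Zero-occupancy bins are `NA`.
#'
#' @param behavior a [behavior_timeseries()].
#' @param trials trial table subset to analyse (stimulation-epoch analyses
#'   should pass good trials only, i.e. those reaching the trigger point).
#' @param variable one of `"lick_rate"`, `"speed"`, `"occupancy"`,
#'   `"decel_events"`.
#' @param geometry a [track_geometry()].
#' @param bin_width bin width, cm.
#' @param decel reuse a precomputed [deceleration_events()] result.
#' @return object of class `behavior_map`: list with `per_trial`
#'   (trials x bins), `trial_avg`, `variable`, `bin_centers`, `trial_ids`.
#' @export
behavior_spatial_map <- function(behavior, trials, variable,
                                 geometry = track_geometry(),
                                 bin_width = 3.03, decel = NULL) {
  if (!variable %in% c("lick_rate", "speed", "occupancy", "decel_events"))
    stop("unknown behavioural variable: ", variable)
  if (!nrow(trials)) stop("empty trial table")
  sr <- attr(behavior, "sample_rate") %||% 100
  nb <- n_bins(bin_width, geometry$track_length)
  if (variable == "decel_events" && is.null(decel))
    decel <- deceleration_events(behavior)
  per <- matrix(NA_real_, nrow(trials), nb)
  for (k in seq_len(nrow(trials))) {
    i <- which(behavior$trial_id == trials$trial_id[k])
    b <- position_bin(behavior$position[i], bin_width, geometry$track_length)
    occ_n <- tabulate(b, nb)
    occ_s <- occ_n / sr
    row <- switch(variable,
      occupancy = occ_s,
      lick_rate = {
        licks <- tabulate(b[behavior$lick[i]], nb)
        r <- licks / occ_s
        r[occ_n == 0] <- NA
        r
      },
      speed = {
        sums <- rep(0, nb)
        agg <- rowsum(behavior$speed[i], b)
        sums[as.integer(rownames(agg))] <- agg
        r <- sums / occ_n
        r
      },
      decel_events = {
        ev <- decel$sample_index[decel$sample_index %in% i]
        tabulate(position_bin(behavior$position[ev], bin_width,
                              geometry$track_length), nb) + 0
      })
    if (variable %in% c("occupancy", "decel_events")) row[occ_n == 0] <- NA
    if (variable == "speed") row[occ_n == 0] <- NA
    per[k, ] <- row
  }
  ta <- colMeans(per, na.rm = TRUE)
  ta[colSums(!is.na(per)) == 0] <- NA
  structure(list(per_trial = per, trial_avg = ta, variable = variable,
                 bin_width = bin_width,
                 bin_centers = bin_centers(bin_width, geometry$track_length),
                 trial_ids = trials$trial_id),
            class = "behavior_map")
}

#' Deceleration events
#'
#' Acceleration is computed across 0.1-s intervals of the running-speed
#' trace; deceleration events are intervals where the acceleration falls
#' below mean - `k_sd` SDs (statistics over the session's in-world
#' samples). Consecutive subthreshold intervals merge into one event,
#' reported at its first sample.
#'
#' @param behavior a [behavior_timeseries()] with >= 10 s of in-world data.
#' @param dt acceleration interval, seconds.
#' @param k_sd threshold in SDs below the mean.
#' @return list with `sample_index` (100-Hz index of each event onset),
#'   `position` (cm), `threshold`, `acceleration` (the decimated trace).
#' @export
deceleration_events <- function(behavior, dt = 0.1, k_sd = 2) {
  sr <- attr(behavior, "sample_rate") %||% 100
  if (sum(behavior$in_world) < 10 * sr)
    stop("deceleration_events: need at least 10 s of in-world data")
  step <- round(dt * sr)
  idx <- seq(1, nrow(behavior), by = step)
  v <- behavior$speed[idx]
  a <- diff(v) / dt
  iw <- behavior$in_world[idx][-1] & behavior$in_world[idx][-length(idx)]
  mu <- mean(a[iw]); s <- sd(a[iw])
  thr <- mu - k_sd * s
  sub <- a < thr & iw
  r <- rle(sub)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ev <- starts[r$values]
  sample_index <- idx[ev + 1]  # sample where the drop lands
  list(sample_index = sample_index,
       position = behavior$position[sample_index],
       threshold = thr, acceleration = a)
}

#' Bin-wise map difference (a - b)
#'
#' Element-wise difference of trial-averaged maps on mutually occupied
#' bins (e.g. stimulation-epoch minus baseline-epoch distribution).
#'
#' @param map_a,map_b `behavior_map`s (or bare vectors) on identical bins.
#' @return numeric vector of differences (`NA` where either is missing).
#' @export
delta_map <- function(map_a, map_b) {
  a <- if (inherits(map_a, "behavior_map")) map_a$trial_avg else map_a
  b <- if (inherits(map_b, "behavior_map")) map_b$trial_avg else map_b
  if (length(a) != length(b)) stop("delta_map: bin mismatch")
  a - b
}

#' Named spatial summary windows
#'
#' The standard summary windows: the 21.21 cm after the stimulation trigger
#' (`post_stim`), the reward zone (`reward_zone`), and the 15.15 cm before
#' the trigger used for deceleration comparisons (`pre_stim_decel`).
#'
#' @param geometry a [track_geometry()].
#' @export
summary_windows <- function(geometry = track_geometry()) {
  sp <- geometry$stim_point
  list(post_stim = c(sp, sp + 21.21),
       reward_zone = geometry$reward_zone,
       pre_stim_decel = c(sp - 15.15, sp))
}

#' Mean of a spatial map within a window
#'
#' Mean over bins whose centre lies inside the window interval.
#'
#' @param map a `behavior_map`, or a numeric vector (then supply
#'   `bin_centers_cm`).
#' @param window `c(lo, hi)` in cm, or a name from [summary_windows()].
#' @param bin_centers_cm bin centres for bare vectors.
#' @param geometry geometry used to resolve named windows.
#' @return scalar mean (`NA` if no occupied bin falls in the window).
#' @export
window_summary <- function(map, window, bin_centers_cm = NULL,
                           geometry = track_geometry()) {
  if (is.character(window)) window <- summary_windows(geometry)[[window]]
  v <- if (inherits(map, "behavior_map")) map$trial_avg else map
  ctr <- if (inherits(map, "behavior_map")) map$bin_centers else bin_centers_cm
  sel <- ctr >= window[1] & ctr <= window[2]
  if (!any(sel & !is.na(v))) return(NA_real_)
  mean(v[sel], na.rm = TRUE)
}

#' Trial-outcome change versus a control session
#'
#' The within-day change in each outcome's proportion (stimulation minus
#' baseline epoch) minus the same change on the matched no-stimulation
#' control day (second minus first epoch), guarding against drift over the
#' session.
#'
#' @param stim_trials trial table of the stimulation day.
#' @param control_trials trial table of the control day (`NULL` returns the
#'   raw delta flagged `controlled = FALSE`).
#' @param epochs_stim,epochs_control epoch sets; the two compared epochs on
#'   the control day default to the same names.
#' @param epoch_pair epochs compared, default `c("baseline", "stim")`.
#' @return data.frame with `outcome`, `delta`, and attribute `controlled`.
#' @export
outcome_delta_vs_control <- function(stim_trials, control_trials,
                                     epochs_stim, epochs_control = epochs_stim,
                                     epoch_pair = c("baseline", "stim")) {
  outs <- c("correct", "fail_lick", "fail_overshoot")
  prop <- function(trials, epochs, name) {
    tt <- epoch_trials(trials, epochs, name)
    tt <- tt[tt$complete, , drop = FALSE]
    if (!nrow(tt)) return(setNames(rep(NA_real_, 3), outs))
    vapply(outs, function(o) mean(tt$outcome == o), numeric(1))
  }
  d_stim <- prop(stim_trials, epochs_stim, epoch_pair[2]) -
    prop(stim_trials, epochs_stim, epoch_pair[1])
  controlled <- !is.null(control_trials)
  d_ctrl <- if (controlled)
    prop(control_trials, epochs_control, epoch_pair[2]) -
      prop(control_trials, epochs_control, epoch_pair[1])
  else setNames(rep(0, 3), outs)
  res <- data.frame(outcome = outs, delta = unname(d_stim - d_ctrl))
  attr(res, "controlled") <- controlled
  res
}

#' Deceleration-peak progression across trial blocks
#'
#' For each sliding block of `block_size` stimulation trials (step 1), the
#' deceleration-event map minus the baseline trial-average is computed and
#' the track bin of maximal increase recorded. The progression of peak
#' location against block index is summarised by the OLS slope and Pearson
#' R-squared, with a permutation null obtained by shuffling the order of
#' the trials feeding the blocks and rebuilding the sliding blocks each
#' time (overlapping blocks share trials, so the trial is the exchangeable
#' unit; permuting the block-peak sequence directly would be
#' anti-conservative). `p_r2` is the fraction of shuffles with R-squared at
#' least the observed value, `p_slope` the fraction with slope at most the
#' observed (an earlier-moving peak gives a negative slope).
#'
#' @param stim_maps `behavior_map` of `decel_events` for stimulation-epoch
#'   good trials.
#' @param baseline_avg baseline trial-averaged deceleration map (vector).
#' @param block_size trials per sliding block.
#' @param n_shuffles permutations of block order (the headline analysis
#'   uses 100,000; tests use fewer with identical machinery).
#' @param seed RNG seed for the permutations.
#' @return list with `peaks_cm`, `block_index`, `slope`, `r2`, `p_slope`,
#'   `p_r2`, `n_blocks`, `n_shuffles`.
#' @export
decel_peak_progression <- function(stim_maps, baseline_avg, block_size = 3,
                                   n_shuffles = 100000, seed = 1) {
  per <- stim_maps$per_trial
  ntr <- nrow(per)
  if (ntr < 5) stop("decel_peak_progression: need at least 5 stimulation trials")
  nblk <- ntr - block_size + 1
  if (nblk < 3) stop("decel_peak_progression: fewer than 3 sliding blocks")
  base <- if (inherits(baseline_avg, "behavior_map")) baseline_avg$trial_avg
    else baseline_avg
  block_peaks <- function(m) vapply(seq_len(nblk), function(b) {
    d <- colMeans(m[b:(b + block_size - 1), , drop = FALSE], na.rm = TRUE) -
      base
    stim_maps$bin_centers[which.max(ifelse(is.na(d), -Inf, d))]
  }, numeric(1))
  peaks <- block_peaks(per)
  x <- seq_len(nblk)
  xc <- x - mean(x)
  denom_x <- sum(xc^2)
  trend <- function(y) {
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    c(r = if (sy == 0) 0 else sum(xc * yc) / (sqrt(denom_x) * sy),
      slope = sum(xc * y) / denom_x)
  }
  obs <- trend(peaks)
  obs_r <- unname(obs["r"]); obs_slope <- unname(obs["slope"])
  set.seed(seed)
  null_r <- null_slope <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    tp <- trend(block_peaks(per[sample.int(ntr), , drop = FALSE]))
    null_r[s] <- tp["r"]
    null_slope[s] <- tp["slope"]
  }
  list(peaks_cm = peaks, block_index = x, slope = obs_slope, r2 = obs_r^2,
       p_r2 = mean(null_r^2 >= obs_r^2 - 1e-12),
       p_slope = mean(null_slope <= obs_slope + 1e-12),
       n_blocks = nblk, n_shuffles = n_shuffles)
}
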