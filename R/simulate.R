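## Synthetic session generator: task-rule-obeying behaviour plus calcium
## traces with planted place fields, stimulation responses, suppression /
## enhancement, and post-epoch remapping, so every analysis stage can be
## checked against ground truth.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of a standard session: 600
#' neurons of which 27% carry place fields (~44 start-zone and ~49
#' reward-zone cells), 15/5/10/5-minute epochs, and running behaviour
#' calibrated so a 10-minute stimulation epoch yields about 19.2 completed
#' good trials.
#'
#' @param n_neurons number of recorded neurons.
#' @param place_fraction fraction of neurons given a place field.
#' @param n_start_pc,n_reward_pc planted counts of start-zone / reward-zone
#'   place cells (among the place cells).
#' @param epochs an [epoch_set()].
#' @param run_speed_mean,run_speed_sd piecewise-constant running speed model
#'   (cm/s); segments last 0.5-1.5 s.
#' @param min_speed lower truncation of segment speeds, cm/s.
#' @param success_p probability a trial is a rewarded (correct) trial.
#' @param fail_lick_share among failures, share that fail by out-zone licking.
#' @param dwell_s required continuous dwell in the reward zone before
#'   reward, seconds.
#' @param in_zone_lick_rate,out_lick_rate,fail_lick_rate Poisson lick rates
#'   (Hz) while dwelling in the zone / while running / on lick-failure
#'   trials.
#' @param stim_lick_delta planted extra lick rate (Hz) inside the
#'   stimulation zone during the stimulation epoch (behavioural effect).
#' @param dark_timeout_s,white_timeout_s,prep_s minimum dark timeout after
#'   success, white timeout after failure, and the lick-free period before
#'   the next trial, seconds.
#' @param slowdown optional planted running slowdown,
#'   `list(center, width, factor, per_trial_shift)` (cm, cm, multiplier,
#'   cm/trial), applied to stimulation-epoch trials; drives deceleration-
#'   progression analyses.
#' @param tau_s calcium indicator decay constant, seconds.
#' @param noise_sd additive dF/F noise SD.
#' @param f0_range per-neuron resting fluorescence range (a.u.).
#' @param field_rate in-field transient event rate at the field centre, Hz.
#' @param baseline_rate out-of-field transient rate, Hz.
#' @param baseline_amp amplitude of baseline transients (dF/F).
#' @param amp_jitter_sdlog lognormal amplitude jitter (sdlog).
#' @param field_width_range,field_amp_range ranges for planted tuning SD
#'   (cm) and peak event amplitude (dF/F).
#' @param stimulate whether the session includes photostimulation.
#' @param n_targets number of targeted neurons.
#' @param target_category planted category targeted (`"reward_pc"`,
#'   `"start_pc"` or `"non_pc"`).
#' @param response_prob,response_amp per-trial probability and dF/F
#'   amplitude of stimulation-evoked transients in targets. The default
#'   amplitude is below the mean planted in-field amplitude so evoked
#'   responses stay smaller than natural place-field activity.
#' @param n_suppressed,suppress_mag,n_enhanced,enhance_mag planted
#'   perturbation of non-targeted place cells after stimulation onset.
#' @param perturb_trial_p per-trial participation probability of the
#'   planted perturbation; competition-driven suppression waxes and wanes
#'   across trials rather than scaling every trial identically (a uniform
#'   multiplicative change would largely be absorbed by within-epoch
#'   standardisation).
#' @param target_perturb planted perturbation of the targeted cells' own
#'   in-field activity after stimulation onset (`"none"`, `"enhanced"` or
#'   `"suppressed"`): reactivating place cells as the animal approaches
#'   their fields can boost (or occlude) their endogenous place response.
#' @param target_perturb_mag magnitude of that perturbation.
#' @param n_offtarget,offtarget_radius_um planted off-target responders
#'   among non-targets, placed within the given distance of a beamlet.
#' @param n_shifted,shift_cm,shift_category planted post-epoch place-field
#'   centre-of-mass displacement (remapping).
#' @param sample_rate,frame_rate behaviour / imaging rates, Hz.
#' @param seed integer seed; mandatory for any stochastic call.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 600, place_fraction = 0.27,
                       n_start_pc = 44, n_reward_pc = 49,
                       epochs = epoch_set(),
                       run_speed_mean = 11.6, run_speed_sd = 2,
                       min_speed = 6,
                       success_p = 0.61, fail_lick_share = 0.15,
                       dwell_s = 3, in_zone_lick_rate = 2,
                       out_lick_rate = 0.08, fail_lick_rate = 2,
                       stim_lick_delta = 0,
                       dark_timeout_s = 5, white_timeout_s = 10, prep_s = 3,
                       slowdown = NULL,
                       tau_s = 0.4, noise_sd = 0.05, f0_range = c(50, 150),
                       field_rate = 2, baseline_rate = 0.05,
                       baseline_amp = 0.4, amp_jitter_sdlog = 0.15,
                       field_width_range = c(6, 14),
                       field_amp_range = c(0.4, 1.0),
                       stimulate = TRUE, n_targets = 15,
                       target_category = "reward_pc",
                       response_prob = 0.8, response_amp = 0.6,
                       n_suppressed = 0, suppress_mag = 0.5,
                       n_enhanced = 0, enhance_mag = 0.5,
                       perturb_trial_p = 0.6,
                       target_perturb = "none", target_perturb_mag = 0.5,
                       n_offtarget = 0, offtarget_radius_um = 15,
                       n_shifted = 0, shift_cm = 0,
                       shift_category = "start_pc",
                       sample_rate = 100, frame_rate = 30,
                       seed = 1) {
  cfg <- as.list(environment())
  if (!stimulate) cfg$n_targets <- 0L
  n_pc <- round(n_neurons * place_fraction)
  if (cfg$n_start_pc + cfg$n_reward_pc > n_pc)
    stop("config: n_start_pc + n_reward_pc exceeds the number of place cells")
  stopifnot(place_fraction >= 0, place_fraction <= 1,
            response_prob >= 0, response_prob <= 1,
            success_p >= 0, success_p <= 1, cfg$n_targets <= n_neurons)
  if (is.null(seed)) stop("config: a seed is mandatory")
  min_trial <- 200 / run_speed_mean + white_timeout_s + prep_s
  if (any(epochs$end - epochs$start < min_trial))
    stop("config: an epoch is shorter than one feasible trial")
  class(cfg) <- "sim_config"
  cfg
}

## --- behaviour -------------------------------------------------------------

# one trial's within-world sample record plus its trailing inter-trial gap
sim_one_trial <- function(cfg, geometry, kind, t0, stim_zone_extra = 0,
                          slowdown_center = NA) {
  sr <- cfg$sample_rate
  dt <- 1 / sr
  rz <- geometry$reward_zone
  seg_speed <- function(n_seg) pmax(cfg$min_speed,
    rnorm(n_seg, cfg$run_speed_mean, cfg$run_speed_sd))
  # running speed profile out to `target` cm (piecewise constant segments)
  run_to <- function(target, v_end = NULL) {
    sp <- numeric(0)
    repeat {
      v <- rep(seg_speed(8), times = round(runif(8, 0.5, 1.5) * sr))
      sp <- c(sp, v)
      if (sum(sp) * dt >= target) break
    }
    if (!is.na(slowdown_center)) {
      pos <- cumsum(sp) * dt
      w <- abs(pos - slowdown_center) < cfg$slowdown$width / 2
      sp[w] <- sp[w] * cfg$slowdown$factor
      # slowed samples cover less ground; extend until target reached
      while (sum(sp) * dt < target) sp <- c(sp, seg_speed(1))
    }
    pos <- cumsum(sp) * dt
    n <- which(pos >= target)[1]
    list(speed = sp[seq_len(n)], pos = pos[seq_len(n)])
  }
  if (kind == "correct") {
    stop_pos <- runif(1, rz[1] + 3, rz[2] - 2)
    decel_d <- 15
    r <- run_to(stop_pos - decel_d)
    v0 <- r$speed[length(r$speed)]
    td <- 2 * decel_d / v0
    nd <- ceiling(td * sr)
    dec_sp <- pmax(v0 * (1 - seq_len(nd) / nd), 0)
    dec_pos <- r$pos[length(r$pos)] + cumsum(dec_sp) * dt
    dwell_n <- round((cfg$dwell_s + runif(1, 0, 1)) * sr)
    post_n <- round(1.0 * sr)
    n_run <- length(r$speed) + nd
    speed <- c(r$speed, dec_sp, rep(0, dwell_n + post_n))
    pos <- c(r$pos, dec_pos, rep(dec_pos[nd], dwell_n + post_n))
    pos <- pmin(pos, geometry$track_length)
    lick <- rep(FALSE, length(speed))
    reward <- rep(FALSE, length(speed))
    # >= 3 licks inside the first 3 s of dwell, plus Poisson extras
    lick_t <- c(0.8, 1.6, 2.4,
                cumsum(rexp(50, max(cfg$in_zone_lick_rate, 1e-6))))
    lick_t <- lick_t[lick_t < dwell_n * dt]
    lick[n_run + unique(pmax(1, round(lick_t * sr)))] <- TRUE
    reward[n_run + round(cfg$dwell_s * sr)] <- TRUE
    # 3 licks after reward end the trial
    lick[n_run + dwell_n + round(c(0.25, 0.5, 0.75) * sr)] <- TRUE
    # sparse licks while running (kept well under the 10-lick failure limit)
    nrl <- min(rpois(1, cfg$out_lick_rate * n_run * dt), 4)
    if (nrl > 0) lick[sample.int(n_run, nrl)] <- TRUE
    timeout <- cfg$dark_timeout_s + runif(1, 0, 2)
  } else if (kind == "fail_overshoot") {
    r <- run_to(geometry$track_length)
    speed <- r$speed
    pos <- pmin(r$pos, geometry$track_length)
    lick <- rep(FALSE, length(speed))
    reward <- rep(FALSE, length(speed))
    in_zone <- pos >= rz[1] & pos <= rz[2]
    nrl <- min(rpois(1, cfg$out_lick_rate * length(speed) * dt), 6)
    if (nrl > 0) {
      cand <- which(!in_zone)
      lick[sample(cand, min(nrl, length(cand)))] <- TRUE
    }
    timeout <- cfg$white_timeout_s + runif(1, 0, 2)
  } else { # fail_lick: trial terminates at the 11th out-of-zone lick
    r <- run_to(geometry$track_length)
    all_pos <- pmin(r$pos, geometry$track_length)
    out_zone <- which(!(all_pos >= rz[1] & all_pos <= rz[2]))
    t11 <- sum(rexp(11, cfg$fail_lick_rate))
    avail <- out_zone[out_zone <= max(2, round(t11 * sr))]
    if (length(avail) < 11) avail <- out_zone
    idx <- sort(sample(avail, 11))  # 11 distinct out-of-zone lick samples
    n_end <- idx[11]
    speed <- r$speed[seq_len(n_end)]
    pos <- all_pos[seq_len(n_end)]
    lick <- rep(FALSE, n_end)
    lick[idx] <- TRUE
    reward <- rep(FALSE, n_end)
    timeout <- cfg$white_timeout_s + runif(1, 0, 2)
  }
  # planted stimulation-zone licking (kept below the failure limit)
  if (stim_zone_extra > 0 && kind != "fail_lick") {
    sz <- geometry$stim_zone
    in_sz <- pos >= sz[1] & pos <= sz[2] & speed > 0
    extra <- which(in_sz & runif(length(pos)) < stim_zone_extra * dt)
    in_zone <- pos >= rz[1] & pos <= rz[2]
    budget <- 9 - sum(lick & !in_zone)
    if (length(extra) > budget) extra <- extra[seq_len(max(budget, 0))]
    lick[extra] <- TRUE
  }
  iti_n <- round((timeout + cfg$prep_s) * sr)
  list(speed = speed, pos = pos, lick = lick, reward = reward, iti_n = iti_n)
}

#' Simulate task behaviour
#'
#' Generates a 100-Hz behaviour timeseries obeying the task rules: reward
#' only after at least 3 s of dwell and 3 licks in the reward zone; a trial
#' terminates at the 11th lick outside the reward zone or at the back wall;
#' successful trials are followed by a dark timeout of at least 5 s and
#' failures by a white timeout of at least 10 s, with a 3-s lick-free period
#' before the next trial (inter-trial samples have `in_world = FALSE`).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param geometry a [track_geometry()].
#' @return list with elements `behavior` (a [behavior_timeseries()]) and
#'   `trials` (the [build_trial_table()] of that behaviour).
#' @export
simulate_behavior <- function(config, seed = config$seed,
                              geometry = track_geometry()) {
  set.seed(seed)
  cfg <- config
  sr <- cfg$sample_rate
  total_n <- round((max(cfg$epochs$end) - min(cfg$epochs$start)) * sr)
  t0 <- min(cfg$epochs$start)
  stim_iv <- if ("stim" %in% cfg$epochs$name)
    epoch_interval(cfg$epochs, "stim") else c(Inf, Inf)
  pos <- speed <- numeric(total_n)
  lick <- reward <- logical(total_n)
  trial_id <- rep(-1L, total_n)
  in_world <- logical(total_n)
  cur <- round(1.0 * sr)  # 1-s lead-in before the first trial
  tid <- 0L
  stim_trial_i <- 0L
  while (cur < total_n) {
    now <- t0 + cur / sr
    in_stim <- now >= stim_iv[1] && now < stim_iv[2]
    kind <- if (runif(1) < cfg$success_p) "correct"
      else if (runif(1) < cfg$fail_lick_share) "fail_lick"
      else "fail_overshoot"
    sl_center <- NA
    if (in_stim) {
      stim_trial_i <- stim_trial_i + 1L
      if (!is.null(cfg$slowdown))
        sl_center <- cfg$slowdown$center -
          cfg$slowdown$per_trial_shift * (stim_trial_i - 1L)
    }
    tr <- sim_one_trial(cfg, geometry, kind, now,
                        stim_zone_extra = if (in_stim) cfg$stim_lick_delta else 0,
                        slowdown_center = sl_center)
    n_tr <- length(tr$speed)
    if (cur + n_tr > total_n) break  # drop the trial the session would cut
    i <- cur + seq_len(n_tr)
    pos[i] <- tr$pos; speed[i] <- tr$speed
    lick[i] <- tr$lick; reward[i] <- tr$reward
    trial_id[i] <- tid; in_world[i] <- TRUE
    tid <- tid + 1L
    cur <- cur + n_tr + tr$iti_n
  }
  beh <- behavior_timeseries(time = t0 + (seq_len(total_n) - 1) / sr,
                             position = pos, speed = speed, lick = lick,
                             reward = reward, trial_id = trial_id,
                             in_world = in_world, sample_rate = sr)
  list(behavior = beh, trials = build_trial_table(beh, geometry))
}

## --- neuron specifications -------------------------------------------------

# planted field extent used for ground-truth zone labels: the 25%-of-peak
# interval of the *expected trial-averaged dF/F map* implied by the
# generative model -- the planted Gaussian event-rate bump convolved with
# the forward exponential calcium kernel (spatial length = running speed x
# decay constant, the kernel smears activity ahead of the field) and the
# pipeline's spatial smoothing (SD 3 bins of 2.27 cm), clipped to the track
planted_field_interval <- function(center, width, kernel_cm = 11.6 * 0.4,
                                   smooth_cm = 3 * 2.27, track_length = 200) {
  x <- seq(-60, track_length + 60, by = 0.1)
  t(mapply(function(c0, w0) {
    g <- dnorm(x, c0, sqrt(w0^2 + smooth_cm^2))
    if (kernel_cm > 0) {
      k <- exp(-(seq(0, 8 * kernel_cm, by = 0.1)) / kernel_cm)
      g <- stats::filter(c(g, numeric(length(k))), k, method = "convolution",
                         sides = 1)[seq_along(x)]
      g[is.na(g)] <- 0
    }
    iv <- range(x[g >= 0.25 * max(g)])
    pmin(pmax(iv, 0), track_length)
  }, center, width))
}

#' Draw per-neuron ground-truth specifications
#'
#' Assigns place fields (with the configured start-zone / reward-zone
#' counts), targets, planted stimulation responses, suppression /
#' enhancement, off-target responders and post-epoch field shifts.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param geometry a [track_geometry()].
#' @return data.frame, one row per neuron, with the planted parameters and
#'   a `truth_category` column (zone label of the planted field).
#' @export
draw_neuron_specs <- function(config, seed = config$seed,
                              geometry = track_geometry()) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_neurons
  n_pc <- round(n * cfg$place_fraction)
  pc_idx <- sort(sample.int(n, n_pc))
  sp <- data.frame(neuron_id = seq_len(n), is_place_cell = FALSE,
                   field_center = NA_real_, field_width = NA_real_,
                   field_amplitude = 0, baseline_rate = cfg$baseline_rate,
                   is_target = FALSE, cluster = NA_integer_,
                   response_prob = 0, response_amp = 0,
                   perturbation = "none", perturb_mag = 0,
                   post_shift = 0, offtarget_of = NA_integer_)
  sp$is_place_cell[pc_idx] <- TRUE
  ns <- min(cfg$n_start_pc, n_pc)
  nr <- min(cfg$n_reward_pc, n_pc - ns)
  start_ids <- pc_idx[seq_len(ns)]
  reward_ids <- pc_idx[ns + seq_len(nr)]
  other_ids <- setdiff(pc_idx, c(start_ids, reward_ids))
  sp$field_center[start_ids] <- runif(ns, 30, 40)
  sp$field_width[start_ids] <- runif(ns, 7, 12)
  sp$field_center[reward_ids] <- runif(nr, 165, 174)
  sp$field_width[reward_ids] <- runif(nr, 7, 12)
  sp$field_center[other_ids] <- runif(length(other_ids), 5, 195)
  sp$field_width[other_ids] <- runif(length(other_ids),
                                     cfg$field_width_range[1],
                                     cfg$field_width_range[2])
  sp$field_amplitude[pc_idx] <- runif(n_pc, cfg$field_amp_range[1],
                                      cfg$field_amp_range[2])
  iv <- matrix(NA_real_, n, 2)
  iv[pc_idx, ] <- planted_field_interval(sp$field_center[pc_idx],
                                         sp$field_width[pc_idx],
                                         kernel_cm = cfg$run_speed_mean * cfg$tau_s,
                                         track_length = geometry$track_length)
  sp$truth_category <- "non_pc"
  sp$truth_category[pc_idx] <- vapply(pc_idx, function(i)
    zone_category(c(iv[i, 1], iv[i, 2]), geometry), character(1))
  if (cfg$stimulate && cfg$n_targets > 0) {
    pool <- if (cfg$target_category == "non_pc") which(!sp$is_place_cell)
      else which(sp$truth_category == cfg$target_category)
    tg <- sample(pool, min(cfg$n_targets, length(pool)))
    sp$is_target[tg] <- TRUE
    sp$cluster[tg] <- (seq_along(tg) - 1L) %% 5L
    sp$response_prob[tg] <- cfg$response_prob
    sp$response_amp[tg] <- cfg$response_amp
    if ((cfg$target_perturb %||% "none") != "none") {
      sp$perturbation[tg] <- cfg$target_perturb
      sp$perturb_mag[tg] <- cfg$target_perturb_mag
    }
  }
  if (cfg$n_offtarget > 0 && any(sp$is_target)) {
    pool <- which(!sp$is_target & !sp$is_place_cell)
    ot <- sample(pool, min(cfg$n_offtarget, length(pool)))
    src <- sample(which(sp$is_target), length(ot), replace = TRUE)
    sp$offtarget_of[ot] <- src
    sp$cluster[ot] <- sp$cluster[src]
    sp$response_prob[ot] <- cfg$response_prob
    sp$response_amp[ot] <- cfg$response_amp
  }
  # Planted suppression/enhancement must be visible to the perturbation
  # assay, which scores activity just after the stimulation zone: perturbed
  # cells are drawn from the unconstrained place cells and their fields
  # repositioned into the window following the zone.
  pert_pool <- setdiff(other_ids, which(sp$is_target))
  reposition <- function(idx) {
    sp$field_center[idx] <<- runif(length(idx), 124, 148)
    sp$field_width[idx] <<- runif(length(idx), 7, 11)
    niv <- planted_field_interval(sp$field_center[idx], sp$field_width[idx],
                                  kernel_cm = cfg$run_speed_mean * cfg$tau_s,
                                  track_length = geometry$track_length)
    sp$truth_category[idx] <<- vapply(seq_along(idx), function(k)
      zone_category(niv[k, ], geometry), character(1))
  }
  if (cfg$n_suppressed > 0) {
    sup <- sample(pert_pool, min(cfg$n_suppressed, length(pert_pool)))
    reposition(sup)
    sp$perturbation[sup] <- "suppressed"
    sp$perturb_mag[sup] <- cfg$suppress_mag
    pert_pool <- setdiff(pert_pool, sup)
  }
  if (cfg$n_enhanced > 0) {
    enh <- sample(pert_pool, min(cfg$n_enhanced, length(pert_pool)))
    reposition(enh)
    sp$perturbation[enh] <- "enhanced"
    sp$perturb_mag[enh] <- cfg$enhance_mag
  }
  if (cfg$n_shifted > 0 && cfg$shift_cm != 0) {
    pool <- which(sp$truth_category == cfg$shift_category & !sp$is_target)
    sh <- sample(pool, min(cfg$n_shifted, length(pool)))
    sp$post_shift[sh] <- cfg$shift_cm
  }
  sp
}

## --- traces ----------------------------------------------------------------

# behaviour interpolated onto the imaging frame grid
behavior_at_frames <- function(behavior, frame_time) {
  sr <- attr(behavior, "sample_rate") %||% 100
  idx <- pmin(pmax(floor((frame_time - behavior$time[1]) * sr) + 1, 1),
              nrow(behavior))
  data.frame(frame = seq_along(frame_time), time = frame_time,
             position = behavior$position[idx], speed = behavior$speed[idx],
             in_world = behavior$in_world[idx],
             trial_id = behavior$trial_id[idx])
}

#' Simulate calcium traces with planted place fields
#'
#' Place fields are generated as Gaussian event-rate modulation of Poisson
#' calcium transients, convolved with a single-exponential indicator kernel
#' (instantaneous rise), plus additive noise; raw fluorescence is
#' `F0 * (1 + dF/F)`. During the post epoch planted field centres are
#' displaced by each neuron's `post_shift` (remapping ground truth).
#'
#' @param behavior a [behavior_timeseries()] covering all epochs.
#' @param specs data.frame from [draw_neuron_specs()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param geometry a [track_geometry()].
#' @return a [trace_matrix()].
#' @export
simulate_traces <- function(behavior, specs, config, seed = config$seed,
                            geometry = track_geometry()) {
  set.seed(seed)
  cfg <- config
  fr <- cfg$frame_rate
  t0 <- behavior$time[1]
  total <- nrow(behavior) / (attr(behavior, "sample_rate") %||% 100)
  nf <- floor(total * fr)
  frame_time <- t0 + (seq_len(nf) - 1) / fr
  fb <- behavior_at_frames(behavior, frame_time)
  post_iv <- if ("post" %in% cfg$epochs$name)
    epoch_interval(cfg$epochs, "post") else c(Inf, Inf)
  in_post <- frame_time >= post_iv[1] & frame_time < post_iv[2]
  gate <- fb$in_world & fb$speed > 1
  n <- nrow(specs)
  alpha <- exp(-1 / (cfg$tau_s * fr))
  f0 <- runif(n, cfg$f0_range[1], cfg$f0_range[2])
  F <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    s <- specs[i, ]
    lam_b <- rep(s$baseline_rate / fr, nf)
    ev_b <- rbinom(nf, 1L, pmin(lam_b, 1))
    sig <- ev_b * cfg$baseline_amp *
      exp(rnorm(nf, 0, cfg$amp_jitter_sdlog))
    if (isTRUE(s$is_place_cell)) {
      ctr <- ifelse(in_post, s$field_center + s$post_shift, s$field_center)
      lam_f <- cfg$field_rate / fr *
        exp(-(fb$position - ctr)^2 / (2 * s$field_width^2)) * gate
      ev_f <- rbinom(nf, 1L, pmin(lam_f, 1))
      sig <- sig + ev_f * s$field_amplitude *
        exp(rnorm(nf, 0, cfg$amp_jitter_sdlog))
    }
    dff <- as.numeric(stats::filter(sig, alpha, method = "recursive")) +
      rnorm(nf, 0, cfg$noise_sd)
    F[i, ] <- f0[i] * (1 + pmax(dff, -0.95))
  }
  # ROI centroids; planted off-target responders sit near their source target
  cent <- cbind(runif(n, 5, 507), runif(n, 5, 507))
  ot <- which(!is.na(specs$offtarget_of))
  if (length(ot)) {
    px_per_um <- 512 / 800
    d <- runif(length(ot), 3, cfg$offtarget_radius_um) * px_per_um
    th <- runif(length(ot), 0, 2 * pi)
    cent[ot, ] <- cent[specs$offtarget_of[ot], ] + d * cbind(cos(th), sin(th))
    cent[ot, ] <- pmin(pmax(cent[ot, ], 0), 511.99)
  }
  trace_matrix(F, frame_rate = fr, frame_time = frame_time,
               roi_centroids = cent, f0 = f0)
}

## --- stimulation -----------------------------------------------------------

#' Apply the photostimulation protocol to simulated traces
#'
#' For every stimulation trial each responder (targets and planted
#' off-target cells) fires a transient of its `response_amp` with
#' probability `response_prob`, time-locked to the completion of its
#' cluster's two illumination intervals. Cells planted as suppressed have
#' their activity (fluorescence above `F0`) scaled down from the bout
#' onset to the end of that trial; cells planted as enhanced gain
#' additional stimulation-coupled transients over that window (an additive
#' change of the spatial activity profile, as seen in stimulus-triggered
#' averages of enhanced cells). Both participate on each trial with
#' probability `perturb_trial_p`. The artifact mask is set for every frame
#' overlapping the 1045-ms bout.
#'
#' @param traces a [trace_matrix()] from [simulate_traces()].
#' @param protocol a [stim_protocol()]; onsets must lie in the stimulation
#'   epoch.
#' @param specs data.frame from [draw_neuron_specs()].
#' @param behavior the session behaviour (trial extents for the
#'   perturbation window).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return the modified [trace_matrix()].
#' @export
apply_stimulation <- function(traces, protocol, specs, behavior, config,
                              seed = config$seed) {
  set.seed(seed)
  cfg <- config
  fr <- traces$frame_rate
  nf <- ncol(traces$F)
  onsets <- protocol$trial_onsets
  if (!length(onsets)) return(traces)
  stim_iv <- epoch_interval(cfg$epochs, "stim")
  if (any(traces$frame_time[onsets] < stim_iv[1] |
          traces$frame_time[onsets] >= stim_iv[2]))
    stop("protocol error: stimulation onset outside the stimulation epoch")
  fb <- behavior_at_frames(behavior, traces$frame_time)
  alpha <- exp(-1 / (cfg$tau_s * fr))
  bout_frames <- ceiling(protocol$bout_ms / 1000 * fr)
  responders <- which(specs$response_prob > 0 & specs$response_amp > 0)
  ev <- matrix(0, length(responders), nf)
  for (j in seq_along(responders)) {
    i <- responders[j]
    cl <- specs$cluster[i]
    offs <- protocol$schedule$off_ms[protocol$schedule$cluster == cl]
    rel <- ceiling(offs / 1000 * fr)
    fire <- runif(length(onsets)) < specs$response_prob[i]
    at <- as.vector(outer(rel, onsets[fire], `+`))
    at <- at[at >= 1 & at <= nf]
    ev[j, at] <- ev[j, at] + specs$response_amp[i]
  }
  if (length(responders)) {
    evoked <- t(apply(ev, 1, function(e)
      as.numeric(stats::filter(e, alpha, method = "recursive"))))
    f0 <- traces$f0 %||% rep(100, nrow(traces$F))
    traces$F[responders, ] <- traces$F[responders, ] +
      f0[responders] * evoked
  }
  # suppression / enhancement from bout onset to the end of that trial,
  # participating on each trial with probability perturb_trial_p
  pert <- which(specs$perturbation != "none" & specs$perturb_mag > 0)
  if (length(pert)) {
    f0 <- traces$f0 %||% rep(100, nrow(traces$F))
    trial_win <- lapply(onsets, function(o) {
      tid <- fb$trial_id[o]
      if (tid < 0) return(integer(0))
      j <- o
      while (j <= nf && fb$trial_id[j] == tid) j <- j + 1
      o:(j - 1)
    })
    p_tr <- cfg$perturb_trial_p %||% 1
    for (i in pert) {
      hit <- runif(length(trial_win)) < p_tr
      win <- unlist(trial_win[hit])
      if (!length(win)) next
      if (specs$perturbation[i] == "suppressed") {
        sc <- 1 - specs$perturb_mag[i]
        traces$F[i, win] <- f0[i] + (traces$F[i, win] - f0[i]) * sc
      } else {
        # enhanced: additive stimulation-coupled transients after onset
        amp <- if (isTRUE(specs$is_place_cell[i])) specs$field_amplitude[i]
          else cfg$baseline_amp
        lam <- specs$perturb_mag[i] * 2 / fr  # events per frame
        e <- numeric(nf)
        e[win] <- rbinom(length(win), 1L, min(lam, 1)) * amp
        add <- as.numeric(stats::filter(e, alpha, method = "recursive"))
        traces$F[i, ] <- traces$F[i, ] + f0[i] * add
      }
    }
  }
  for (o in onsets) {
    hi <- min(nf, o + bout_frames - 1)
    traces$artifact_mask[o:hi] <- TRUE
  }
  traces
}

## --- full session ----------------------------------------------------------

#' Simulate a complete session with ground truth
#'
#' Composes [simulate_behavior()], [draw_neuron_specs()],
#' [simulate_traces()] and [apply_stimulation()] into a four-epoch session.
#' Identical `(config, seed)` give bit-identical sessions.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param geometry a [track_geometry()].
#' @return list with `session` (a [session_data()]) and `truth` (planted
#'   specs, target/suppressed/enhanced/shifted ids, planted lick delta).
#' @export
make_session <- function(config, seed = config$seed,
                         geometry = track_geometry()) {
  cfg <- config
  cfg$seed <- seed
  beh <- simulate_behavior(cfg, seed = seed, geometry = geometry)
  specs <- draw_neuron_specs(cfg, seed = seed + 1L, geometry = geometry)
  traces <- simulate_traces(beh$behavior, specs, cfg, seed = seed + 2L,
                            geometry = geometry)
  protocol <- NULL
  if (cfg$stimulate && any(specs$is_target)) {
    tg <- which(specs$is_target)
    onsets <- stim_onset_frames(beh$behavior, beh$trials, cfg$epochs,
                                geometry, traces$frame_time)
    um_per_px <- 800 / 512
    protocol <- stim_protocol(
      target_ids = tg, cluster_assignment = specs$cluster[tg],
      trial_onsets = onsets,
      beamlet_xy = traces$roi_centroids[tg, , drop = FALSE] * um_per_px)
    if (length(onsets))
      traces <- apply_stimulation(traces, protocol, specs, beh$behavior,
                                  cfg, seed = seed + 3L)
  }
  sess <- session_data(beh$behavior, traces, cfg$epochs, geometry,
                       protocol = protocol, trials = beh$trials,
                       meta = list(session_type =
                         if (cfg$stimulate) cfg$target_category else "no_stim",
                         seed = seed))
  truth <- list(specs = specs,
                target_ids = which(specs$is_target),
                offtarget_ids = which(!is.na(specs$offtarget_of)),
                suppressed_ids = which(specs$perturbation == "suppressed"),
                enhanced_ids = which(specs$perturbation == "enhanced"),
                shifted_ids = which(specs$post_shift != 0),
                shift_cm = cfg$shift_cm,
                stim_lick_delta = cfg$stim_lick_delta)
  list(session = sess, truth = truth)
}

#' Frame indices of trigger-point crossings
#'
#' For every good trial whose crossing of the stimulation point falls
#' inside the epoch named `"stim"` of `epochs`, the imaging-frame index of
#' that crossing. Also used with a pseudo-epoch over the baseline period
#' to build the no-stimulation control for off-target screening.
#'
#' @param behavior a [behavior_timeseries()].
#' @param trials its trial table.
#' @param epochs an [epoch_set()] containing an epoch named `stim`.
#' @param geometry a [track_geometry()].
#' @param frame_time imaging frame times, seconds.
#' @return integer frame indices (1-based).
#' @export
stim_onset_frames <- function(behavior, trials, epochs, geometry, frame_time) {
  iv <- epoch_interval(epochs, "stim")
  tt <- trials[trials$start_time >= iv[1] & trials$start_time < iv[2] &
               trials$reached_stim_point, , drop = FALSE]
  onsets <- integer(0)
  for (k in seq_len(nrow(tt))) {
    i <- which(behavior$trial_id == tt$trial_id[k] &
               behavior$position >= geometry$stim_point)
    if (!length(i)) next
    t_cross <- behavior$time[i[1]]
    if (t_cross < iv[1] || t_cross >= iv[2]) next  # trigger armed in-epoch only
    f <- findInterval(t_cross, frame_time)
    if (f >= 1 && f <= length(frame_time)) onsets <- c(onsets, f)
  }
  onsets
}
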