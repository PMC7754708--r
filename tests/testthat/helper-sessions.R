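# Shared fixtures built in code: small simulated sessions (cached within a
# test run) and an independent task-rule replay oracle.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small four-epoch stimulation session used across modules
small_session <- function() cached("small", {
  cfg <- sim_config(n_neurons = 80, n_start_pc = 10, n_reward_pc = 10,
                    epochs = epoch_set(c(baseline = 300, pre = 200,
                                         stim = 400, post = 200)),
                    n_targets = 8, n_suppressed = 6, seed = 101)
  make_session(cfg)
})

# medium session with a large place-cell population for latent analyses
latent_config <- function(seed, response_amp = 0.6, response_prob = 0.8,
                          n_suppressed = 15, suppress_mag = 0.5) {
  sim_config(n_neurons = 120, place_fraction = 0.55,
             n_start_pc = 12, n_reward_pc = 16,
             epochs = epoch_set(c(baseline = 180, pre = 210,
                                  stim = 420, post = 120)),
             n_targets = 15, response_amp = response_amp,
             response_prob = response_prob,
             n_suppressed = n_suppressed, suppress_mag = suppress_mag,
             seed = seed)
}

# dF/F + frame-aligned behaviour + running mask for a session
session_frames <- function(session) {
  dff <- compute_dff(session$traces)
  fb <- optoplace:::behavior_at_frames(session$behavior,
                                       session$traces$frame_time)
  list(dff = dff, fb = fb,
       vmask = velocity_mask(session$behavior, session$traces$frame_time),
       ep = epoch_of(fb$time, session$epochs))
}

epoch_map <- function(session, sf, name, ...) {
  tt <- epoch_trials(session$trials, session$epochs, name)
  spatial_tuning_map(sf$dff, sf$fb, sf$vmask & sf$ep == name,
                     session$geometry, trial_ids = tt$trial_id, ...)
}

# Independent replay of the task rules over the raw event log. Returns the
# number of violations of (1) reward delivered without >= 3 s contiguous
# in-zone dwell or >= 3 in-zone licks since zone entry, and (2) a trial
# continuing more than a sample beyond its 11th out-of-zone lick.
replay_rule_violations <- function(behavior, geometry = track_geometry()) {
  sr <- attr(behavior, "sample_rate")
  rz <- geometry$reward_zone
  bad <- 0L
  for (id in unique(behavior$trial_id[behavior$trial_id >= 0])) {
    i <- which(behavior$trial_id == id)
    pos <- behavior$position[i]
    in_zone <- pos >= rz[1] & pos <= rz[2]
    licks <- behavior$lick[i]
    rewards <- which(behavior$reward[i])
    for (r in rewards) {
      # contiguous in-zone dwell ending at the reward sample
      k <- r
      while (k > 1 && in_zone[k - 1]) k <- k - 1
      dwell <- (r - k + 1) / sr
      n_licks <- sum(licks[k:r] & in_zone[k:r])
      if (dwell < 3 - 1e-9 || n_licks < 3) bad <- bad + 1L
    }
    out_licks <- which(licks & !in_zone)
    if (length(out_licks) >= 11 && (length(i) - out_licks[11]) > 2)
      bad <- bad + 1L
  }
  bad
}

# hand-built behaviour timeseries for rule edge cases: one in-world segment
# with the given per-sample columns, padded by inter-trial samples
manual_behavior <- function(position, lick = FALSE, reward = FALSE,
                            speed = 10, trial_id = 0L, sr = 100) {
  n <- length(position)
  pad <- 20
  behavior_timeseries(
    time = (seq_len(n + 2 * pad) - 1) / sr,
    position = c(rep(0, pad), position, rep(0, pad)),
    speed = c(rep(0, pad), rep_len(speed, n), rep(0, pad)),
    lick = c(rep(FALSE, pad), rep_len(lick, n), rep(FALSE, pad)),
    reward = c(rep(FALSE, pad), rep_len(reward, n), rep(FALSE, pad)),
    trial_id = c(rep(-1L, pad), rep_len(trial_id, n), rep(-1L, pad)),
    in_world = c(rep(FALSE, pad), rep(TRUE, n), rep(FALSE, pad)),
    sample_rate = sr)
}

# place_map object built directly from a trial-average profile (and optional
# per-trial maps); bypasses the simulator for arithmetic-level tests
manual_place_map <- function(trial_avg, per_trial = NULL, bin_width = 2.27,
                             n_trials = 8, noise_sd = 0) {
  if (is.null(dim(trial_avg))) trial_avg <- matrix(trial_avg, nrow = 1)
  nn <- nrow(trial_avg); nb <- ncol(trial_avg)
  if (is.null(per_trial)) {
    per_trial <- array(NA_real_, c(nn, n_trials, nb))
    for (k in seq_len(n_trials))
      per_trial[, k, ] <- trial_avg +
        matrix(rnorm(nn * nb, 0, noise_sd), nn, nb)
    trial_avg <- apply(per_trial, c(1, 3), mean)
  }
  structure(list(per_trial = per_trial, trial_avg = trial_avg,
                 trial_ids = seq_len(dim(per_trial)[2]) - 1L,
                 bin_width = bin_width, n_bins = nb,
                 bin_centers = (seq_len(nb) - 0.5) * bin_width,
                 smoothing_sd_bins = 0),
            class = "place_map")
}

# brute-force per-frame sliding-percentile dF/F (independent oracle)
brute_force_dff <- function(F, window_s = 10, percentile = 8, fr = 30) {
  half <- round(window_s * fr / 2)
  n <- ncol(F)
  t(sapply(seq_len(nrow(F)), function(i) sapply(seq_len(n), function(t) {
    w <- F[i, max(1, t - half):min(n, t + half)]
    f0 <- quantile(w, percentile / 100, type = 7, names = FALSE)
    (F[i, t] - f0) / f0
  })))
}
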