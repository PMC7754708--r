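# Generator: rule enforcement, determinism, planted tuning and calibration.

short_epochs <- epoch_set(c(baseline = 120, pre = 120, stim = 240, post = 120))

test_that("success probability 1 yields only correct trials obeying dwell+lick", {
  cfg <- sim_config(n_neurons = 5, place_fraction = 0.6, n_start_pc = 1,
                    n_reward_pc = 1, success_p = 1, epochs = short_epochs, stimulate = FALSE,
                    seed = 3)
  b <- simulate_behavior(cfg)
  expect_true(all(b$trials$outcome == "correct"))
  expect_true(all(b$trials$n_licks_in_zone >= 3))
  rz <- track_geometry()$reward_zone
  for (id in b$trials$trial_id) {
    i <- which(b$behavior$trial_id == id)
    in_zone <- b$behavior$position[i] >= rz[1] & b$behavior$position[i] <= rz[2]
    r <- which(b$behavior$reward[i])[1]
    k <- r
    while (k > 1 && in_zone[k - 1]) k <- k - 1
    expect_gte((r - k + 1) / 100, 3)  # >= 3 s contiguous dwell before reward
  }
})

test_that("a forced high out-zone lick rate fails every trial by licking", {
  cfg <- sim_config(n_neurons = 5, place_fraction = 0.6, n_start_pc = 1,
                    n_reward_pc = 1, success_p = 0, fail_lick_share = 1,
                    epochs = short_epochs, stimulate = FALSE, seed = 4)
  b <- simulate_behavior(cfg)
  expect_true(all(b$trials$outcome == "fail_lick"))
  expect_true(all(b$trials$n_licks_out_zone == 11))
})

test_that("task-rule replay finds no violations across seeds", {
  for (s in 1:5) {
    cfg <- sim_config(n_neurons = 5, place_fraction = 0.6, n_start_pc = 1,
                      n_reward_pc = 1, epochs = short_epochs, stimulate = FALSE,
                      stim_lick_delta = if (s > 3) 2 else 0, seed = 200 + s)
    b <- simulate_behavior(cfg)
    expect_equal(replay_rule_violations(b$behavior), 0L)
  }
})

test_that("identical config and seed give bit-identical sessions", {
  cfg <- sim_config(n_neurons = 20, place_fraction = 0.4, n_start_pc = 3,
                    n_reward_pc = 3,
                    epochs = short_epochs, n_targets = 3, seed = 11)
  a <- make_session(cfg)
  b <- make_session(cfg)
  expect_identical(a$session$behavior, b$session$behavior)
  expect_identical(a$session$traces$F, b$session$traces$F)
  expect_identical(a$truth, b$truth)
})

test_that("planted place-cell fraction and no-stim protocol behave as configured", {
  cfg <- sim_config(n_neurons = 40, place_fraction = 0.27, n_start_pc = 4,
                    n_reward_pc = 4, epochs = short_epochs,
                    stimulate = FALSE, seed = 12)
  ms <- make_session(cfg)
  expect_equal(sum(ms$truth$specs$is_place_cell), round(40 * 0.27))
  expect_null(ms$session$protocol)
  expect_false(any(ms$session$traces$artifact_mask))
})

test_that("a flat-spec neuron's trace is baseline plus noise only", {
  cfg <- sim_config(n_neurons = 2, place_fraction = 0, n_start_pc = 0,
                    n_reward_pc = 0, baseline_rate = 0, noise_sd = 0.02,
                    epochs = short_epochs, stimulate = FALSE, seed = 13)
  ms <- make_session(cfg)
  f <- ms$session$traces$F[1, ]
  f0 <- ms$session$traces$f0[1]
  expect_lt(max(abs(f / f0 - 1)), 0.12)  # pure noise around F0
  expect_equal(mean(f / f0 - 1), 0, tolerance = 0.01)
})

test_that("recovered tuning peaks match the generative expectation", {
  # single noiseless place cell: the expected dF/F profile is the planted
  # Gaussian smeared forward by the calcium kernel; the measured map peak
  # must land within one bin of the oracle profile's peak
  cfg <- sim_config(n_neurons = 1, place_fraction = 1, n_start_pc = 0,
                    n_reward_pc = 0, noise_sd = 0, baseline_rate = 0,
                    field_rate = 6,
                    epochs = epoch_set(c(baseline = 420, pre = 60,
                                         stim = 60, post = 60)),
                    stimulate = FALSE, seed = 21)
  ms <- make_session(cfg)
  sp <- ms$truth$specs
  sf <- session_frames(ms$session)
  map <- epoch_map(ms$session, sf, "baseline")
  peak_cm <- map$bin_centers[which.max(map$trial_avg[1, ])]
  x <- seq(0, 200, by = 0.1)
  g <- dnorm(x, sp$field_center[1], sqrt(sp$field_width[1]^2 + (3 * 2.27)^2))
  L <- cfg$run_speed_mean * cfg$tau_s
  k <- exp(-seq(0, 8 * L, by = 0.1) / L)
  prof <- stats::filter(c(g, numeric(length(k))), k, method = "convolution",
                        sides = 1)[seq_along(x)]
  oracle_peak <- x[which.max(prof)]
  expect_lt(abs(peak_cm - oracle_peak), 2.27)
})

test_that("a planted +30 cm post shift moves the post-epoch tuning peak", {
  cfg <- sim_config(n_neurons = 1, place_fraction = 1, n_start_pc = 1,
                    n_reward_pc = 0, noise_sd = 0, baseline_rate = 0,
                    field_rate = 6, n_shifted = 1, shift_cm = 30,
                    shift_category = "start_pc",
                    epochs = epoch_set(c(baseline = 60, pre = 300,
                                         stim = 60, post = 300)),
                    stimulate = FALSE, seed = 22)
  ms <- make_session(cfg)
  sf <- session_frames(ms$session)
  pre <- epoch_map(ms$session, sf, "pre")
  post <- epoch_map(ms$session, sf, "post")
  d <- post$bin_centers[which.max(post$trial_avg[1, ])] -
    pre$bin_centers[which.max(pre$trial_avg[1, ])]
  expect_equal(d, 30, tolerance = 2.27 / 30)
})

test_that("planted stimulation responses appear at the planted amplitude", {
  ms <- cached("stim_resp", {
    cfg <- sim_config(n_neurons = 30, place_fraction = 0.5, n_start_pc = 4,
                      n_reward_pc = 6, epochs = short_epochs, n_targets = 5,
                      response_prob = 1, response_amp = 0.5,
                      noise_sd = 0.01, seed = 31)
    make_session(cfg)
  })
  prot <- ms$session$protocol
  tens <- extract_peristim(ms$session$traces, prot$trial_onsets)
  windows <- response_windows(prot)
  rec <- classify_responsive(tens, windows)
  tg <- prot$target_ids
  amps <- attr(rec, "trial_amplitudes")[tg, , drop = FALSE]
  # response_prob 1: every trial responds near the planted 0.5 in the
  # preferred window (window mean of an instantaneous-rise decaying transient)
  expect_true(all(rowMeans(amps > 0.25) > 0.9))
  expect_true(all(rec$responsive[tg]))
})

test_that("evoked responses stay below endogenous place-field activity", {
  ms <- small_session()
  sf <- session_frames(ms$session)
  map <- epoch_map(ms$session, sf, "baseline")
  pc <- which(ms$truth$specs$is_place_cell)
  # natural in-field response magnitude: per-trial peak dF/F while the
  # animal crosses the planted field (the comparable quantity to a
  # peri-stimulus response amplitude)
  sp <- ms$truth$specs
  field_peak <- mean(vapply(pc, function(i) {
    infield <- abs(sf$fb$position - sp$field_center[i]) <
      2 * sp$field_width[i]
    sel <- infield & sf$ep == "baseline" & sf$fb$trial_id >= 0
    tr <- sf$fb$trial_id[sel]
    mean(vapply(split(sf$dff[i, sel], tr), max, numeric(1)))
  }, numeric(1)))
  prot <- ms$session$protocol
  rec <- classify_responsive(extract_peristim(ms$session$traces,
                                              prot$trial_onsets),
                             response_windows(prot))
  evoked <- mean(rec$mean_amplitude[prot$target_ids])
  expect_lt(evoked, field_peak)
})

test_that("suppression halves post-onset in-field activity of perturbed cells", {
  # one session, stimulation applied twice to the same base traces: once
  # with the planted suppression, once with it switched off
  cfg <- sim_config(n_neurons = 30, place_fraction = 0.6, n_start_pc = 2,
                    n_reward_pc = 8, epochs = short_epochs, n_targets = 4,
                    n_suppressed = 8, suppress_mag = 0.5,
                    perturb_trial_p = 1, noise_sd = 0, seed = 33)
  beh <- simulate_behavior(cfg, seed = 33)
  specs <- draw_neuron_specs(cfg, seed = 34)
  traces <- simulate_traces(beh$behavior, specs, cfg, seed = 35)
  tg <- which(specs$is_target)
  onsets <- stim_onset_frames(beh$behavior, beh$trials, cfg$epochs,
                              track_geometry(), traces$frame_time)
  prot <- stim_protocol(target_ids = tg,
                        cluster_assignment = specs$cluster[tg],
                        trial_onsets = onsets,
                        beamlet_xy = traces$roi_centroids[tg, ] * 800 / 512)
  on <- apply_stimulation(traces, prot, specs, beh$behavior, cfg, seed = 36)
  specs_off <- specs
  specs_off$perturbation <- "none"
  off <- apply_stimulation(traces, prot, specs_off, beh$behavior, cfg,
                           seed = 36)
  sup <- which(specs$perturbation == "suppressed")
  expect_gte(length(sup), 4)
  fb <- optoplace:::behavior_at_frames(beh$behavior, traces$frame_time)
  post_onset <- rep(FALSE, ncol(traces$F))
  for (o in onsets) {
    tid <- fb$trial_id[o]
    j <- o
    while (j <= length(post_onset) && fb$trial_id[j] == tid) j <- j + 1
    post_onset[o:(j - 1)] <- TRUE
  }
  f0 <- traces$f0
  act_on <- rowMeans((on$F[sup, post_onset, drop = FALSE] - f0[sup]) / f0[sup])
  act_off <- rowMeans((off$F[sup, post_onset, drop = FALSE] - f0[sup]) / f0[sup])
  expect_equal(act_on / act_off, rep(0.5, length(sup)), tolerance = 1e-8)
})


test_that("stimulation-epoch good-trial counts centre on the configured mean", {
  n <- vapply(1:10, function(s) {
    b <- simulate_behavior(sim_config(seed = s), seed = 400 + s)
    iv <- epoch_interval(epoch_set(), "stim")
    tt <- b$trials
    sum(tt$start_time >= iv[1] & tt$start_time < iv[2] &
        tt$reached_stim_point & tt$complete)
  }, numeric(1))
  expect_gt(mean(n), 16)
  expect_lt(mean(n), 23)
})
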