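# Behavioural spatial maps, deceleration statistics, deltas, summaries,
# outcome deltas, and the deceleration-peak progression.

test_that("lick-rate maps are zero off-zone and occupancy conserves duration", {
  n <- 2000
  pos <- seq(0, 199.9, length.out = n)
  rz <- track_geometry()$reward_zone
  lick <- pos >= rz[1] & pos <= rz[2] & (seq_len(n) %% 10 == 0)
  b <- manual_behavior(pos, lick = lick)
  tt <- build_trial_table(b)
  m <- behavior_spatial_map(b, tt, "lick_rate")
  nz <- which(m$trial_avg > 0)
  expect_true(all(m$bin_centers[nz] >= rz[1] - 3.03 &
                  m$bin_centers[nz] <= rz[2] + 3.03))
  occ <- behavior_spatial_map(b, tt, "occupancy")
  expect_equal(sum(occ$per_trial[1, ], na.rm = TRUE), n / 100)
  # total licks conserved: sum(rate * occupancy) = lick count
  expect_equal(sum(m$per_trial[1, ] * occ$per_trial[1, ], na.rm = TRUE),
               sum(lick))
})

test_that("deceleration events threshold at mean - 2 SD and merge runs", {
  n <- 6000
  sp <- rep(15, n)
  b0 <- manual_behavior(cumsum(sp) / 100 %% 200, speed = sp)
  expect_length(deceleration_events(b0)$sample_index, 0)
  # one sharp stop in otherwise constant running
  sp1 <- sp; sp1[3000:3100] <- 0
  pos1 <- pmin(cumsum(sp1) / 100, 199)
  b1 <- manual_behavior(pos1, speed = sp1)
  ev <- deceleration_events(b1)
  expect_length(ev$sample_index, 1)
  # stop planted at trial sample 3000 (+20 lead-in samples)
  expect_lt(abs(ev$sample_index - 3021), 15)
  # affine invariance: doubling all speeds keeps event locations
  b2 <- manual_behavior(pos1, speed = 2 * sp1)
  expect_equal(deceleration_events(b2)$sample_index, ev$sample_index)
})

test_that("delta maps are antisymmetric and recover planted differences", {
  a <- c(1, 2, 3, NA, 5); b <- c(1, 1, 1, 1, 1)
  expect_equal(delta_map(a, b), c(0, 1, 2, NA, 4))
  expect_equal(delta_map(a, b), -delta_map(b, a))
  expect_error(delta_map(a, b[1:3]), "bin mismatch")
})

test_that("window summaries average bins whose centres fall inside", {
  v <- rep(NA_real_, 66)
  ctr <- (seq_len(66) - 0.5) * 3.03
  v[10:12] <- c(1, 2, 3)
  win <- c(ctr[10] - 0.1, ctr[12] + 0.1)
  expect_equal(window_summary(v, win, bin_centers_cm = ctr), 2)
  expect_equal(window_summary(rep(7, 66), c(50, 80), bin_centers_cm = ctr), 7)
  # the 18.6-cm reward zone spans 6 bins of 3.03 cm
  rz <- summary_windows()$reward_zone
  expect_equal(sum(ctr >= rz[1] & ctr <= rz[2]), 6)
  expect_true(is.na(window_summary(v, c(180, 190), bin_centers_cm = ctr)))
})

test_that("a planted stimulation-zone lick increase is recovered", {
  deltas <- vapply(1:12, function(s) {
    cfg <- sim_config(stim_lick_delta = 2,
                      epochs = epoch_set(c(baseline = 300, pre = 60,
                                           stim = 300, post = 60)),
                      stimulate = FALSE, n_neurons = 2, n_start_pc = 0,
                      n_reward_pc = 0, seed = 500 + s)
    b <- simulate_behavior(cfg, seed = 500 + s)
    good <- function(name) {
      tt <- epoch_trials(b$trials, cfg$epochs, name)
      tt[tt$reached_stim_point & tt$complete, , drop = FALSE]
    }
    d <- delta_map(behavior_spatial_map(b$behavior, good("stim"), "lick_rate"),
                   behavior_spatial_map(b$behavior, good("baseline"), "lick_rate"))
    window_summary(d, "post_stim", bin_centers_cm = (seq_len(66) - 0.5) * 3.03)
  }, numeric(1))
  expect_equal(mean(deltas), 2, tolerance = 0.15)
})

test_that("outcome deltas subtract the control-day drift and sum to zero", {
  mk_trials <- function(outcomes, start) {
    data.frame(trial_id = seq_along(outcomes) - 1L,
               start_time = start + seq_along(outcomes) * 10,
               end_time = start + seq_along(outcomes) * 10 + 5,
               outcome = outcomes, complete = TRUE,
               reached_stim_point = TRUE,
               max_position = 200, n_licks_in_zone = 3L,
               n_licks_out_zone = 0L)
  }
  ep <- epoch_set(c(baseline = 500, stim = 500))
  stim_day <- rbind(mk_trials(c(rep("correct", 6), rep("fail_lick", 4)), 0),
                    mk_trials(c(rep("correct", 4), rep("fail_lick", 6)), 500))
  ctrl_day <- rbind(mk_trials(c(rep("correct", 6), rep("fail_lick", 4)), 0),
                    mk_trials(c(rep("correct", 6), rep("fail_lick", 4)), 500))
  d <- outcome_delta_vs_control(stim_day, ctrl_day, ep,
                                epoch_pair = c("baseline", "stim"))
  expect_equal(d$delta[d$outcome == "fail_lick"], 0.2)
  expect_equal(d$delta[d$outcome == "correct"], -0.2)
  expect_equal(sum(d$delta), 0)
  # identical proportions everywhere -> all-zero deltas
  d0 <- outcome_delta_vs_control(ctrl_day, ctrl_day, ep,
                                 epoch_pair = c("baseline", "stim"))
  expect_equal(d0$delta, rep(0, 3))
  d1 <- outcome_delta_vs_control(stim_day, NULL, ep,
                                 epoch_pair = c("baseline", "stim"))
  expect_false(attr(d1, "controlled"))
})

# behaviour-map stand-in with chosen per-trial deceleration maps
decel_map_fixture <- function(per_trial) {
  structure(list(per_trial = per_trial,
                 trial_avg = colMeans(per_trial, na.rm = TRUE),
                 variable = "decel_events", bin_width = 3.03,
                 bin_centers = (seq_len(ncol(per_trial)) - 0.5) * 3.03,
                 trial_ids = seq_len(nrow(per_trial)) - 1L),
            class = "behavior_map")
}

test_that("the deceleration-peak progression detects a planted moving peak", {
  nb <- 66
  base <- rep(0.1, nb)
  # peak moves exactly one bin earlier per trial (noiseless construction)
  per <- t(sapply(1:12, function(tr) {
    v <- rep(0.1, nb); v[40 - tr] <- 2; v
  }))
  res <- decel_peak_progression(decel_map_fixture(per), base,
                                n_shuffles = 1000, seed = 5)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_lt(res$slope, 0)
  expect_lte(res$p_r2, 5 / 1000)
  expect_lte(res$p_slope, 5 / 1000)
  # constant peaks: no trend, R^2 defined as 0
  per0 <- t(sapply(1:12, function(tr) { v <- rep(0.1, nb); v[30] <- 2; v }))
  res0 <- decel_peak_progression(decel_map_fixture(per0), base,
                                 n_shuffles = 200, seed = 5)
  expect_equal(res0$r2, 0)
  expect_equal(res0$slope, 0)
})

test_that("block-permutation p-values are valid under a shuffled-order null", {
  set.seed(99)
  ps <- vapply(1:60, function(r) {
    per <- matrix(rpois(15 * 66, 0.3), 15, 66) +
      matrix(rnorm(15 * 66, 0, 1e-6), 15, 66)  # continuous tie-break
    decel_peak_progression(decel_map_fixture(per), rep(0.3, 66),
                           n_shuffles = 400, seed = r)$p_r2
  }, numeric(1))
  # validity: P(p <= alpha) <= alpha + 1/n_shuffles, checked at two levels
  expect_lte(mean(ps <= 0.05), 0.05 + 1 / 400 + 2.5 * sqrt(0.05 * 0.95 / 60))
  expect_lte(mean(ps <= 0.2), 0.2 + 1 / 400 + 2.5 * sqrt(0.2 * 0.8 / 60))
})
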