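# Peri-stimulus extraction, response windows, responsive classification,
# off-target screening, stability slope, efficacy.

# minimal trace_matrix with given raw rows
mk_traces <- function(F, artifact = NULL) {
  trace_matrix(F, frame_rate = 30, artifact_mask = artifact)
}

test_that("peristim traces normalise by the frames 5-29 baseline", {
  F <- matrix(100, 2, 400)
  F[1, 210:215] <- 150  # response frames after an onset at 201
  tens <- extract_peristim(mk_traces(F), onsets = 201)
  expect_equal(dim(tens$x), c(2, 1, 150))
  expect_equal(tens$x[2, 1, ], rep(0, 150))
  expect_equal(tens$x[1, 1, tens$rel_frames %in% 9:14], rep(0.5, 6))
  # constant trace -> identically zero
  expect_equal(max(abs(tens$x[2, 1, ])), 0)
  # onset too close to the start is dropped
  expect_warning(expect_error(extract_peristim(mk_traces(F), onsets = 10),
                              "no usable"), "edge")
})

test_that("the 10 response windows follow the cluster schedule", {
  p <- stim_protocol(target_ids = 1:5, cluster_assignment = 0:4)
  w <- response_windows(p)
  expect_equal(nrow(w), 10)
  # window k opens at ceil((105*(k+1) - 5) ms * 30/1000) frames after onset
  expect_equal(w$from, sapply(0:9, function(k) ceiling((105 * (k + 1) - 5) * 0.03)))
  # pairwise non-overlapping, ordered in time
  expect_true(all(w$from[-1] > w$to[-10]))
  expect_equal(p$bout_ms, 1045)
  expect_equal(as.integer(table(w$cluster)), rep(2L, 5))
})

test_that("preferred window is the trial-averaged argmax with earliest tie-break", {
  p <- stim_protocol(target_ids = 1, cluster_assignment = 0L)
  w <- response_windows(p)
  F <- matrix(100, 2, 600)
  # neuron 1: response only in window 3 (frames 13-15 after onset)
  for (o in c(101, 301)) F[1, o + 13:15] <- 160
  # neuron 2: equal responses in windows 2 and 7
  for (o in c(101, 301)) { F[2, o + 10:12] <- 160; F[2, o + 26:28] <- 160 }
  tens <- extract_peristim(mk_traces(F), onsets = c(101, 301))
  pw <- preferred_window(tens, w)
  expect_equal(pw[1], 3)
  expect_equal(pw[2], 2)
})

test_that("responsive calling uses strict inequalities on both thresholds", {
  p <- stim_protocol(target_ids = 1, cluster_assignment = 0L)
  w <- response_windows(p)
  onsets <- seq(101, by = 200, length.out = 10)
  mk <- function(amp, n_hit) {
    F <- matrix(100, 1, 2200)
    for (o in onsets[seq_len(n_hit)])
      F[1, o + 3:5] <- 100 * (1 + amp)  # window 0 frames
    extract_peristim(mk_traces(F), onsets)
  }
  expect_true(classify_responsive(mk(0.5, 4), w)$responsive)    # 40% > 30%
  expect_false(classify_responsive(mk(0.5, 3), w)$responsive)   # 30% not > 30%
  expect_false(classify_responsive(mk(0.40, 10), w)$responsive) # 0.40 not > 0.40
  expect_true(classify_responsive(mk(0.41, 10), w)$responsive)
  # permutation of trial order leaves the call unchanged
  tens <- mk(0.5, 4)
  perm <- sample(10)
  tens$x <- tens$x[, perm, , drop = FALSE]
  tens$artifact <- tens$artifact[perm, , drop = FALSE]
  expect_true(classify_responsive(tens, w)$responsive)
})

test_that("artifact-flagged frames can be excluded from window statistics", {
  p <- stim_protocol(target_ids = 1, cluster_assignment = 0L)
  w <- response_windows(p)
  F <- matrix(100, 1, 1000)
  onsets <- c(101, 401, 701)
  art <- rep(FALSE, 1000)
  for (o in onsets) {
    F[1, o + 3] <- 400      # a contaminated spike in window 0, frame 1 of 3
    F[1, o + 4:5] <- 120    # the clean remainder of the window
    art[o + 3] <- TRUE
  }
  tens <- extract_peristim(mk_traces(F, art), onsets)
  amp_all <- optoplace:::window_amplitude(tens, w$from[1], w$to[1], FALSE)
  amp_cln <- optoplace:::window_amplitude(tens, w$from[1], w$to[1], TRUE)
  expect_equal(unname(amp_cln[1, ]), rep(0.2, 3))
  expect_gt(amp_all[1, 1], 1)
})

test_that("off-target screening needs response, no-stim silence, and proximity", {
  rec <- data.frame(neuron_id = 1:4, responsive = c(TRUE, TRUE, TRUE, FALSE),
                    is_target = c(FALSE, FALSE, FALSE, FALSE))
  ns <- data.frame(neuron_id = 1:4, responsive = c(FALSE, TRUE, FALSE, FALSE))
  um_per_px <- 800 / 512
  beam <- matrix(c(100, 100), 1)  # um
  cent <- rbind(c(100 + 10, 100), c(100, 100), c(100 + 31, 100),
                c(100, 100)) / um_per_px  # px
  got <- detect_off_target(rec, ns, beam, cent)
  expect_equal(got, 1L)  # 10 um, silent in no-stim -> off-target
  # cell 2 responsive in no-stim epochs; cell 3 at 31 um; cell 4 not responsive
  expect_false(any(c(2, 3, 4) %in% got))
  # boundary: exactly 30 um is included (conservative limit)
  cent30 <- rbind(c(130, 100)) / um_per_px
  expect_equal(detect_off_target(rec[1, ], ns[1, ], beam, cent30), 1L)
})

test_that("planted off-target responders are recovered on a synthetic session", {
  ms <- cached("offtarget", {
    cfg <- sim_config(n_neurons = 60, n_start_pc = 6, n_reward_pc = 10,
                      epochs = epoch_set(c(baseline = 120, pre = 120,
                                           stim = 300, post = 60)),
                      n_targets = 8, n_offtarget = 6,
                      response_prob = 0.9, seed = 55)
    make_session(cfg)
  })
  s <- ms$session
  prot <- s$protocol
  rec <- classify_responsive(extract_peristim(s$traces, prot$trial_onsets),
                             response_windows(prot),
                             is_target = seq_len(60) %in% prot$target_ids)
  got <- detect_off_target(rec, NULL, prot$beamlet_xy, s$traces$roi_centroids)
  planted <- ms$truth$offtarget_ids
  expect_gte(sum(planted %in% got) / length(planted), 0.9)
})

test_that("stability slope is exact on linear amplitude sequences", {
  expect_equal(response_stability_slope(rep(0.5, 10))$slope, 0)
  y <- 0.5 - 0.01 * (1:20)
  expect_equal(response_stability_slope(y)$slope, -0.01)
})

test_that("efficacy combines specificity, count, and amplitude", {
  e <- stimulation_efficacy(10, 2, 12, 0.6)
  expect_equal(e$specificity, 2 / 3, tolerance = 1e-4)
  expect_equal(e$efficacy, 4.8)
  expect_equal(stimulation_efficacy(5, 5, 10, 0.7)$efficacy, 0)
  # sign flips under swapping start and reward labels
  expect_equal(stimulation_efficacy(2, 10, 12, 0.6)$efficacy, -4.8)
  expect_true(is.na(stimulation_efficacy(0, 0, 0, 0.5)$efficacy))
})
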