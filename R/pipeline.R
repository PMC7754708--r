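## Session-level orchestration (simulate -> analyze -> report) and
## cohort-level statistics. Every number in the report is computed by the
## module functions; thresholds used are logged in the summary.

#' Run the full analysis pipeline on one session
#'
#' Orchestrates dF/F conversion, tuning maps per epoch, place-field
#' detection and zone classification, photostimulation response analysis
#' (with no-stimulation control and off-target screening), behavioural
#' maps and deltas, latent-factor divergence with suppressed/enhanced
#' calling, and pre/post remapping. Deterministic given the session and
#' seed.
#'
#' @param session a [session_data()] or path to a saved session.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param seed seed for shuffle-based analyses.
#' @param n_factors latent factors (skipped when too few place cells).
#' @param n_shuffles translation shuffles for the reward-zone peak null.
#' @param criteria [field_criteria()].
#' @param run_latent,run_remapping,run_response analysis toggles.
#' @return a `pipeline_report` list: tables per analysis family plus a
#'   machine-readable `summary`.
#' @export
run_pipeline <- function(session, out_dir = NULL, seed = 1,
                         n_factors = 10, n_shuffles = 2000,
                         criteria = field_criteria(),
                         run_latent = TRUE, run_remapping = TRUE,
                         run_response = TRUE) {
  if (is.character(session)) session <- load_session(session)
  geom <- session$geometry
  epochs <- session$epochs
  trials <- session$trials %||% build_trial_table(session$behavior, geom)
  dff <- compute_dff(session$traces)
  fb <- behavior_at_frames(session$behavior, session$traces$frame_time)
  vmask <- velocity_mask(session$behavior, session$traces$frame_time)
  ep_frames <- epoch_of(fb$time, epochs)
  map_for <- function(name) {
    tt <- epoch_trials(trials, epochs, name)
    spatial_tuning_map(dff, fb, vmask & ep_frames == name, geom,
                       trial_ids = tt$trial_id)
  }
  maps <- lapply(setNames(epochs$name, epochs$name), map_for)
  fields <- detect_place_fields(maps$baseline, criteria)
  categories <- classify_zone(fields, nrow(dff), geom)
  has_stim <- length(session$protocol$target_ids) > 0 &&
    length(session$protocol$trial_onsets) > 0
  response <- NULL
  if (run_response && has_stim) {
    prot <- session$protocol
    windows <- response_windows(prot, session$traces$frame_rate)
    is_tg <- seq_len(nrow(dff)) %in% prot$target_ids
    clus <- rep(NA_integer_, nrow(dff))
    clus[prot$target_ids] <- prot$cluster_assignment
    tens <- extract_peristim(session$traces, prot$trial_onsets)
    rec <- classify_responsive(tens, windows, is_target = is_tg,
                               cluster = clus)
    # identical analysis at trigger-point crossings of the no-stimulation
    # baseline epoch guards against tuned endogenous activity
    ns_onsets <- stim_onset_frames(session$behavior, trials,
                                   epoch_set(c(stim = diff(
                                     epoch_interval(epochs, "baseline"))),
                                     start = epoch_interval(epochs, "baseline")[1]),
                                   geom, session$traces$frame_time)
    ns_rec <- if (length(ns_onsets) >= 5)
      classify_responsive(extract_peristim(session$traces, ns_onsets),
                          windows, is_target = is_tg, cluster = clus)
    else NULL
    off_t <- detect_off_target(rec, ns_rec, prot$beamlet_xy,
                               session$traces$roi_centroids)
    resp_t <- which(rec$responsive & rec$is_target)
    amps <- attr(rec, "trial_amplitudes")
    slope <- if (length(resp_t) && ncol(amps) >= 5)
      response_stability_slope(amps[resp_t, , drop = FALSE])$slope
    else NA_real_
    cat_of <- categories$category
    nR <- sum(rec$responsive & cat_of == "reward_pc")
    nS <- sum(rec$responsive & cat_of == "start_pc")
    nT <- sum(rec$responsive)
    eff <- stimulation_efficacy(nR, nS, nT,
      mean(rec$mean_amplitude[rec$responsive]))
    response <- list(records = rec, no_stim_records = ns_rec,
                     off_target_ids = off_t, stability_slope = slope,
                     n_responsive = nT, n_responsive_reward = nR,
                     n_responsive_start = nS,
                     specificity = eff$specificity, efficacy = eff$efficacy)
  }
  # behavioural maps: baseline vs stimulation epoch, good trials only
  good <- function(name) {
    tt <- epoch_trials(trials, epochs, name)
    tt[tt$reached_stim_point & tt$complete, , drop = FALSE]
  }
  decel <- deceleration_events(session$behavior)
  beh <- list()
  for (v in c("lick_rate", "speed", "occupancy", "decel_events")) {
    beh[[v]] <- list(
      baseline = behavior_spatial_map(session$behavior, good("baseline"), v,
                                      geom, decel = decel),
      stim = behavior_spatial_map(session$behavior, good("stim"), v, geom,
                                  decel = decel))
    beh[[v]]$delta <- delta_map(beh[[v]]$stim, beh[[v]]$baseline)
  }
  lick_delta_stim_window <- window_summary(
    beh$lick_rate$delta, "post_stim",
    bin_centers_cm = beh$lick_rate$baseline$bin_centers, geometry = geom)
  latent <- NULL
  if (run_latent) {
    cells <- which(categories$category != "non_pc")
    if (session$meta$session_type %||% "" == "non_pc" && has_stim)
      cells <- setdiff(cells, session$protocol$target_ids)
    if (length(cells) > 2 * (n_factors + 2)) {
      latent <- tryCatch({
        pm <- prepare_population_matrix(dff[cells, , drop = FALSE], cells,
                                        fb, epochs,
                                        session$traces$artifact_mask, geom,
                                        use_epochs = c("baseline", "pre",
                                                       "stim"))
        model <- fit_latent_model(pm, n_factors)
        div <- if (has_stim) trajectory_divergence(model, pm) else NULL
        elig <- select_analysis_cells(model, pm)
        scores <- if (sum(elig) >= 10) perturbation_scores(pm, elig) else NULL
        list(pm_rows = nrow(pm$X), n_cells = length(pm$cell_ids),
             model = model, divergence = div, eligible = elig,
             perturbation = scores)
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }
  remap <- NULL
  if (run_remapping) {
    keep <- suppressWarnings(stability_filter(maps$baseline, maps$pre))
    shifts <- com_shift(maps$pre, maps$post, categories, keep)
    pc <- which(categories$category != "non_pc")
    shuffle <- if (length(pc) >= 10)
      reward_zone_peak_shuffle(maps$post$trial_avg[pc, , drop = FALSE],
                               geom$reward_zone, maps$post$bin_centers,
                               n_shuffles = n_shuffles, seed = seed)
    else NULL
    remap <- list(keep = keep, shifts = shifts, shuffle = shuffle)
  }
  outcome_counts <- table(factor(
    trials$outcome[trials$complete],
    levels = c("correct", "fail_lick", "fail_overshoot")))
  summary <- list(
    session_type = session$meta$session_type %||% "unknown",
    seed = seed,
    thresholds = list(dff_percentile = 8, dff_window_s = 10,
                      speed_cm_s = 5, bin_cm = 2.27, smooth_sd_bins = 3,
                      field_criteria = criteria, response_amp = 0.40,
                      response_frac = 0.30, offtarget_um = 30,
                      stability_r = 0.3, n_factors = n_factors),
    n_neurons = nrow(dff),
    n_trials = sum(trials$complete),
    outcome_counts = as.list(outcome_counts),
    n_place_cells = sum(categories$category != "non_pc"),
    n_start_pc = sum(categories$category == "start_pc"),
    n_reward_pc = sum(categories$category == "reward_pc"),
    lick_delta_stim_window = lick_delta_stim_window,
    n_responsive = response$n_responsive %||% NA,
    specificity = response$specificity %||% NA,
    efficacy = response$efficacy %||% NA,
    stability_slope = response$stability_slope %||% NA,
    n_off_target = length(response$off_target_ids %||% integer()),
    divergence_detected = latent$divergence$detected %||% NA,
    n_suppressed = if (!is.null(latent$perturbation))
      sum(latent$perturbation$class == "suppressed") else NA,
    n_enhanced = if (!is.null(latent$perturbation))
      sum(latent$perturbation$class == "enhanced") else NA,
    reward_peak_count = remap$shuffle$observed %||% NA,
    reward_peak_p = remap$shuffle$p %||% NA)
  report <- list(maps = maps, fields = fields, categories = categories,
                 response = response, behavior = beh,
                 latent = latent, remapping = remap, trials = trials,
                 summary = summary)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_trial_table(report$trials, file.path(out_dir, "trials.csv"))
  export_classification(report$categories, report$fields,
                        file.path(out_dir, "classification.csv"))
  if (!is.null(report$response))
    write.csv(as.data.frame(report$response$records),
              file.path(out_dir, "responses.csv"), row.names = FALSE)
  if (!is.null(report$remapping))
    write.csv(report$remapping$shifts$records,
              file.path(out_dir, "com_shifts.csv"), row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Cohort statistics over session summaries
#'
#' Orchestrates standard nonparametric tests and correlations over
#' per-session metrics: paired or unpaired Wilcoxon tests between two
#' metric columns and Pearson correlations (R-squared reported as the
#' squared correlation). Bonferroni correction is applied over the tests
#' marked as one family.
#'
#' @param metrics data.frame, one row per session.
#' @param tests list of `list(name, a, b, method)` with method one of
#'   `"wilcoxon_paired"`, `"wilcoxon_unpaired"`, `"correlation"`.
#' @param bonferroni logical: correct p-values across the supplied tests.
#' @return data.frame with `name`, `method`, `n`, `estimate`, `p`
#'   (and `p_adj` when corrected); skipped tests carry `NA` and a note.
#' @export
cross_session_stats <- function(metrics, tests, bonferroni = FALSE) {
  if (nrow(metrics) < 2) stop("cross_session_stats: need >= 2 sessions")
  rows <- lapply(tests, function(ts) {
    a <- metrics[[ts$a]]
    b <- if (!is.null(ts$b)) metrics[[ts$b]] else NULL
    ok <- is.finite(a) & (if (is.null(b)) TRUE else is.finite(b))
    note <- ""
    est <- p <- NA_real_
    n <- sum(ok)
    if (n < 2) {
      note <- "insufficient sessions"
    } else if (ts$method == "wilcoxon_paired") {
      w <- suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE))
      est <- median(a[ok] - b[ok]); p <- w$p.value
      if (is.nan(p) || all(a[ok] == b[ok])) { p <- 1; note <- "no difference" }
    } else if (ts$method == "wilcoxon_unpaired") {
      w <- suppressWarnings(wilcox.test(a[ok], b[ok]))
      est <- median(a[ok]) - median(b[ok]); p <- w$p.value
    } else if (ts$method == "correlation") {
      ct <- cor.test(a[ok], b[ok])
      est <- unname(ct$estimate); p <- ct$p.value
    } else stop("unknown test method: ", ts$method)
    data.frame(name = ts$name, method = ts$method, n = n, estimate = est,
               r2 = if (ts$method == "correlation") est^2 else NA_real_,
               p = p, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_adj <- pmin(1, out$p * sum(!is.na(out$p)))
  out
}
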