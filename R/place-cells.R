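## Place-field detection from trial-resolved tuning maps and zone
## classification (Start-PC / Reward-PC / stimulation-zone / other / non-PC).

#' Place-field detection criteria
#'
#' Candidate fields are maximal contiguous runs of bins whose
#' trial-averaged dF/F exceeds baseline + 25% of (peak - baseline). A
#' candidate is accepted iff its width lies within the configured bounds,
#' its in-field mean is at least `in_out_ratio` times the out-of-field
#' mean, it shows significant in-field activity on at least
#' `active_trial_frac` of trials (in-field dF/F above that trial's
#' out-of-field mean + 2 SD), and its peak dF/F reaches `min_peak_dff`
#' (0.20, the anti-false-positive floor). No bootstrap is used.
#'
#' @param rel_threshold run threshold as a fraction of (peak - baseline).
#' @param width_cm `c(min, max)` accepted field width, cm.
#' @param in_out_ratio minimum in-field / out-field mean ratio.
#' @param active_trial_frac minimum fraction of trials with significant
#'   in-field activity.
#' @param active_sd per-trial significance threshold in out-of-field SDs.
#' @param min_peak_dff minimum field peak dF/F.
#' @export
field_criteria <- function(rel_threshold = 0.25, width_cm = c(9, 120),
                           in_out_ratio = 3, active_trial_frac = 0.25,
                           active_sd = 2, min_peak_dff = 0.20) {
  if (width_cm[1] >= width_cm[2])
    stop("field criteria: width bounds must satisfy lo < hi")
  as.list(environment())
}

#' Detect place fields
#'
#' @param place_map a `place_map` from [spatial_tuning_map()] (at least 5
#'   trials recommended).
#' @param criteria a [field_criteria()] list.
#' @return data.frame with one row per accepted field: `neuron_id`,
#'   `field_lo`, `field_hi` (cm, half-open), `peak_dff`, `peak_bin`,
#'   `in_out_ratio`, `active_trial_fraction`, `com` (cm).
#' @export
detect_place_fields <- function(place_map, criteria = field_criteria()) {
  ta <- place_map$trial_avg
  bw <- place_map$bin_width
  ctr <- place_map$bin_centers
  nn <- nrow(ta)
  out <- list()
  for (i in seq_len(nn)) {
    v <- ta[i, ]
    occ <- !is.na(v)
    if (sum(occ) < 3) next
    base <- min(v[occ]); pk <- max(v[occ])
    if (pk <= base) next
    thr <- base + criteria$rel_threshold * (pk - base)
    above <- !is.na(v) & v >= thr
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs)) next
    in_any <- above
    for (k in runs) {
      b <- starts[k]:ends[k]
      width <- length(b) * bw
      if (width < criteria$width_cm[1] || width > criteria$width_cm[2]) next
      out_b <- which(occ & !in_any)
      in_mean <- mean(v[b])
      out_mean <- if (length(out_b)) mean(v[out_b]) else 0
      ratio <- if (out_mean > 0) in_mean / out_mean else Inf
      if (ratio < criteria$in_out_ratio) next
      if (max(v[b]) < criteria$min_peak_dff) next
      # per-trial significance of in-field activity
      pt <- place_map$per_trial[i, , , drop = FALSE]
      ntr <- dim(pt)[2]
      act <- vapply(seq_len(ntr), function(tr) {
        row <- pt[1, tr, ]
        o <- row[setdiff(which(!is.na(row)), b)]
        f <- row[b][!is.na(row[b])]
        if (!length(f) || length(o) < 3) return(FALSE)
        s <- sd(o)
        if (!is.finite(s)) return(FALSE)
        max(f) > mean(o) + criteria$active_sd * s
      }, logical(1))
      frac <- mean(act)
      if (frac < criteria$active_trial_frac) next
      w <- pmax(v[b], 0)
      com <- if (sum(w) > 0) sum(ctr[b] * w) / sum(w) else mean(ctr[b])
      out[[length(out) + 1]] <- data.frame(
        neuron_id = i, field_lo = (b[1] - 1) * bw, field_hi = b[length(b)] * bw,
        peak_dff = max(v[b]), peak_bin = b[which.max(v[b])],
        in_out_ratio = ratio, active_trial_fraction = frac, com = com)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(neuron_id = integer(), field_lo = numeric(),
                  field_hi = numeric(), peak_dff = numeric(),
                  peak_bin = integer(), in_out_ratio = numeric(),
                  active_trial_fraction = numeric(), com = numeric())
}

# zone label of one field interval: a zone is claimed when the field covers
# strictly more than half of the zone's length
zone_category <- function(field, geometry) {
  cover <- function(zone) {
    ov <- max(0, min(field[2], zone[2]) - max(field[1], zone[1]))
    ov / (zone[2] - zone[1])
  }
  eps <- 1e-9  # strict > 50%: exact half-coverage does not claim the zone
  cs <- cover(geometry$start_zone)
  cr <- cover(geometry$reward_zone)
  cz <- cover(geometry$stim_zone)
  if (cs > 0.5 + eps || cr > 0.5 + eps) {
    if (cr >= cs && cr > 0.5 + eps) "reward_pc" else "start_pc"
  } else if (cz > 0.5 + eps) "stim_zone_pc" else "other_pc"
}

#' Classify cells into track-zone categories
#'
#' A cell is a Reward-PC if some accepted field covers more than 50% of the
#' reward zone's length, a Start-PC analogously for the start zone, and a
#' stimulation-zone PC for the configured stimulation zone; start/reward
#' take precedence over the stimulation zone (ties between start and reward
#' resolved by the larger coverage). Cells with fields claiming no zone are
#' `other_pc`; cells with no accepted field are `non_pc`.
#'
#' @param fields data.frame from [detect_place_fields()].
#' @param n_neurons total number of neurons.
#' @param geometry a [track_geometry()].
#' @return data.frame `neuron_id`, `category`.
#' @export
classify_zone <- function(fields, n_neurons, geometry = track_geometry()) {
  cat <- rep("non_pc", n_neurons)
  prec <- c(start_pc = 3, reward_pc = 3, stim_zone_pc = 2, other_pc = 1)
  for (k in seq_len(nrow(fields))) {
    i <- fields$neuron_id[k]
    z <- zone_category(c(fields$field_lo[k], fields$field_hi[k]), geometry)
    if (cat[i] == "non_pc" || prec[z] > prec[cat[i]]) cat[i] <- z
  }
  data.frame(neuron_id = seq_len(n_neurons), category = cat,
             stringsAsFactors = FALSE)
}

#' Centre of mass of a trial-averaged map
#'
#' Locates a cell's place field as the COM of its map's supra-threshold
#' calcium activity: weights are the map above `floor + rel_floor *
#' (peak - floor)`, clipped at zero (the same relative threshold that
#' delimits candidate fields). A sliding-percentile dF/F baseline leaves
#' a positive pedestal across the whole track, and scattered baseline
#' transients add off-field mass; weighting the raw map would drag every
#' COM toward the track midpoint. Flat or empty maps return `NA`.
#'
#' @param trial_avg numeric vector (one map) or neurons x bins matrix.
#' @param bin_centers_cm bin centre positions, cm.
#' @param rel_floor relative threshold of the map's range subtracted
#'   before weighting (0 subtracts only the map minimum).
#' @return COM in cm (vector, one per map).
#' @export
place_field_com <- function(trial_avg, bin_centers_cm, rel_floor = 0.25) {
  if (is.null(dim(trial_avg))) trial_avg <- matrix(trial_avg, nrow = 1)
  apply(trial_avg, 1, function(v) {
    occ <- !is.na(v)
    if (!sum(occ)) return(NA_real_)
    lo <- min(v[occ])
    thr <- lo + rel_floor * (max(v[occ]) - lo)
    w <- pmax(v[occ] - thr, 0)
    if (sum(w) == 0) return(NA_real_)
    sum(bin_centers_cm[occ] * w) / sum(w)
  })
}

#' Across-epoch map stability filter
#'
#' Cells are kept iff the Pearson correlation of their trial-averaged maps
#' across the two epochs (over mutually occupied bins) is at least `r_min`
#' (default 0.3); cells with fewer than 3 mutually occupied bins are
#' excluded with a warning.
#'
#' @param map_a,map_b `place_map`s on identical bins (e.g. baseline and
#'   pre-stimulation epochs).
#' @param r_min minimum correlation to keep a cell.
#' @return logical keep-flag per neuron; the correlations are attached as
#'   attribute `"r"`.
#' @export
stability_filter <- function(map_a, map_b, r_min = 0.3) {
  r <- prepost_map_correlation(map_a, map_b)
  if (any(is.na(r)))
    warning(sum(is.na(r)), " cell(s) with < 3 mutually occupied bins excluded")
  keep <- !is.na(r) & r >= r_min
  attr(keep, "r") <- r
  keep
}

#' Export a classification table to CSV
#' @param categories data.frame from [classify_zone()].
#' @param fields data.frame from [detect_place_fields()].
#' @param path output file.
#' @export
export_classification <- function(categories, fields, path) {
  first <- fields[!duplicated(fields$neuron_id), ]
  m <- merge(categories, first, by = "neuron_id", all.x = TRUE)
  write.csv(m[order(m$neuron_id), ], path, row.names = FALSE)
  invisible(path)
}
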