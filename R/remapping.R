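## Pre/post remapping: map correlations, COM distributions and their
## kernel-density peaks, per-cell COM shifts, and the reward-zone
## peak-count translation-shuffle null.

#' Pearson correlation of trial-averaged maps per cell
#'
#' Correlation over mutually occupied bins; cells with fewer than 3 such
#' bins return `NA`.
#'
#' @param pre_map,post_map `place_map`s (or trial-average matrices) on
#'   identical bins.
#' @return numeric vector, one r per neuron.
#' @export
prepost_map_correlation <- function(pre_map, post_map) {
  a <- if (inherits(pre_map, "place_map")) pre_map$trial_avg else pre_map
  b <- if (inherits(post_map, "place_map")) post_map$trial_avg else post_map
  if (is.null(dim(a))) { a <- matrix(a, 1); b <- matrix(b, 1) }
  stopifnot(all(dim(a) == dim(b)))
  vapply(seq_len(nrow(a)), function(i) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(a[i, ok], b[i, ok]))
  }, numeric(1))
}

#' Peak of a COM distribution
#'
#' The mode of a normal-kernel density (rule-of-thumb bandwidth) fitted to
#' the centre-of-mass sample, located on a 0.5-cm grid over the track.
#'
#' @param coms COM values, cm (>= 10 required).
#' @param track_length track length, cm.
#' @param grid_step evaluation grid step, cm.
#' @return peak position in cm (`NA` with a warning for small samples).
#' @export
com_distribution_peak <- function(coms, track_length = 200, grid_step = 0.5) {
  coms <- coms[is.finite(coms)]
  if (length(coms) < 10) {
    warning("com_distribution_peak: fewer than 10 COMs; returning NA")
    return(NA_real_)
  }
  bw <- bw.nrd0(coms)
  d <- density(coms, bw = bw, from = 0, to = track_length,
               n = round(track_length / grid_step) + 1)
  d$x[which.max(d$y)]
}

#' Per-cell and per-category COM shifts
#'
#' Builds the pre/post centre-of-mass record for cells passing the
#' stability filter and summarises signed and absolute shifts per zone
#' category. Group comparisons are delegated to standard tests in reports.
#'
#' @param pre_map,post_map `place_map`s of the pre and post epochs.
#' @param categories data.frame from [classify_zone()].
#' @param keep logical per neuron (stability filter), default all.
#' @return list with `records` (`neuron_id`, `category`, `com_pre`,
#'   `com_post`, `shift`, `prepost_r`) and `summary` (per category: n,
#'   median signed and absolute shift).
#' @export
com_shift <- function(pre_map, post_map, categories, keep = NULL) {
  nn <- nrow(pre_map$trial_avg)
  keep <- keep %||% rep(TRUE, nn)
  ctr <- pre_map$bin_centers
  com_pre <- place_field_com(pre_map$trial_avg, ctr)
  com_post <- place_field_com(post_map$trial_avg, ctr)
  r <- prepost_map_correlation(pre_map, post_map)
  rec <- data.frame(neuron_id = seq_len(nn),
                    category = categories$category,
                    com_pre = com_pre, com_post = com_post,
                    shift = com_post - com_pre, prepost_r = r)
  rec <- rec[keep & is.finite(rec$shift), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(rec, rec$category), function(g)
    data.frame(category = g$category[1], n = nrow(g),
               median_shift = median(g$shift),
               median_abs_shift = median(abs(g$shift)))))
  rownames(summ) <- NULL
  list(records = rec, summary = summ)
}

#' Reward-zone peak-count shuffle null
#'
#' Counts cells whose trial-averaged map peak lies inside a zone, against a
#' null in which every cell's map is independently circularly translated
#' along the track by a uniform offset (mass-preserving) and the peaks
#' recounted. A bounded non-circular variant clips offsets so maps stay on
#' the track.
#'
#' @param trial_avg neurons x bins trial-averaged maps (place cells of the
#'   epoch).
#' @param zone `c(lo, hi)` in cm.
#' @param bin_centers_cm bin centre positions.
#' @param n_shuffles number of translations.
#' @param seed RNG seed.
#' @param circular circular (default) or bounded translation.
#' @return list with `observed`, `null` (counts per shuffle), `null_mean`,
#'   `null_q` (2.5/50/97.5% quantiles), `p` (empirical, add-one rule).
#' @export
reward_zone_peak_shuffle <- function(trial_avg, zone, bin_centers_cm,
                                     n_shuffles = 10000, seed = 1,
                                     circular = TRUE) {
  set.seed(seed)
  nb <- length(bin_centers_cm)
  peak_bin <- apply(trial_avg, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(ifelse(is.na(v), -Inf, v)))
  in_zone <- function(b) {
    p <- bin_centers_cm[b]
    sum(p >= zone[1] & p <= zone[2], na.rm = TRUE)
  }
  observed <- in_zone(peak_bin)
  nn <- nrow(trial_avg)
  null <- integer(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    if (circular) {
      off <- sample.int(nb, nn, replace = TRUE) - 1L
      shifted <- ((peak_bin - 1L + off) %% nb) + 1L
    } else {
      # bounded variant: translation constrained to keep the map on the
      # track, i.e. the peak lands uniformly on 1..nb without wrap
      shifted <- sample.int(nb, nn, replace = TRUE)
    }
    null[s] <- in_zone(shifted)
  }
  list(observed = observed, null = null, null_mean = mean(null),
       null_q = quantile(null, c(0.025, 0.5, 0.975)),
       p = (1 + sum(null >= observed)) / (n_shuffles + 1))
}

#' Circularly translate a map (utility used by the shuffle null)
#' @param v numeric map vector.
#' @param offset bins to shift rightwards.
#' @export
translate_map <- function(v, offset) {
  nb <- length(v)
  off <- ((offset %% nb) + nb) %% nb
  if (off == 0) v else c(v[(nb - off + 1):nb], v[1:(nb - off)])
}
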