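## Latent-factor representation of place-cell population activity:
## population matrix construction, 10-factor model, stimulation-vs-pre
## trajectory divergence, eligibility filtering, and decile-based
## suppressed/enhanced cell calling.

#' Build the (trial, bin) x cells population matrix
#'
#' Imaging frames acquired during stimulation (artifact-masked) are
#' removed; each cell's dF/F is z-scored within each epoch over its
#' remaining in-trial frames (before binning) and then averaged per
#' (trial, spatial bin). Spatial bins that receive any artifact-masked
#' frame on any trial form the "stimulation zone" of the latent analysis
#' and are excluded in every epoch so trajectories stay comparable.
#'
#' @param dff neurons x frames dF/F matrix (rows = the analysed cell set;
#'   for place-cell-stimulation sessions this includes the targets).
#' @param cell_ids ids of the rows of `dff`.
#' @param frame_behavior frame-aligned behaviour (position, trial_id).
#' @param epochs an [epoch_set()]; epoch names to include via `use_epochs`.
#' @param artifact_mask logical per frame.
#' @param geometry a [track_geometry()].
#' @param bin_width spatial bin width, cm.
#' @param use_epochs epochs entering the matrix.
#' @return object of class `population_matrix`: list with `X` (rows x
#'   cells, z-scored binned activity), `rows` (data.frame epoch / trial /
#'   bin), `cell_ids`, `excluded_bins`, `bin_centers`.
#' @export
prepare_population_matrix <- function(dff, cell_ids, frame_behavior, epochs,
                                      artifact_mask,
                                      geometry = track_geometry(),
                                      bin_width = 2.27,
                                      use_epochs = c("baseline", "pre",
                                                     "stim")) {
  nb <- n_bins(bin_width, geometry$track_length)
  fb <- frame_behavior
  ep <- epoch_of(fb$time, epochs)
  in_trial <- fb$trial_id >= 0 & !artifact_mask
  # bins contaminated by stimulation frames, across all trials
  art_frames <- which(fb$trial_id >= 0 & artifact_mask)
  excluded_bins <- sort(unique(position_bin(fb$position[art_frames],
                                            bin_width, geometry$track_length)))
  blocks <- list(); rows <- list()
  for (e in use_epochs) {
    sel <- which(in_trial & ep == e)
    if (!length(sel)) stop("epoch '", e, "' has no clean in-trial frames")
    z <- t(scale(t(dff[, sel, drop = FALSE])))  # z per cell within epoch
    b <- position_bin(fb$position[sel], bin_width, geometry$track_length)
    tr <- fb$trial_id[sel]
    key <- interaction(tr, b, drop = TRUE)
    agg <- t(rowsum(t(z), group = key) / as.vector(table(key)))
    ks <- strsplit(colnames(agg), "\\.")
    kt <- as.integer(vapply(ks, `[`, "", 1))
    kb <- as.integer(vapply(ks, `[`, "", 2))
    keep <- !(kb %in% excluded_bins)
    ord <- order(kt[keep], kb[keep])
    blocks[[e]] <- t(agg[, keep, drop = FALSE][, ord, drop = FALSE])
    rows[[e]] <- data.frame(epoch = e, trial = kt[keep][ord], bin = kb[keep][ord])
  }
  X <- do.call(rbind, blocks)
  rowdf <- do.call(rbind, rows)
  rownames(X) <- NULL; rownames(rowdf) <- NULL
  v <- apply(X, 2, sd, na.rm = TRUE)
  dropped <- which(!is.finite(v) | v < 1e-8)
  if (length(dropped)) {
    warning("dropping ", length(dropped), " near-zero-variance cell(s)")
    X <- X[, -dropped, drop = FALSE]
    cell_ids <- cell_ids[-dropped]
  }
  ok <- complete.cases(X)
  structure(list(X = X[ok, , drop = FALSE], rows = rowdf[ok, , drop = FALSE],
                 cell_ids = cell_ids, excluded_bins = excluded_bins,
                 bin_width = bin_width,
                 bin_centers = bin_centers(bin_width, geometry$track_length)),
            class = "population_matrix")
}

#' Fit the latent factor model
#'
#' Maximum-likelihood common-factor decomposition (default 10 factors,
#' unrotated) with factor scores by the regression method; uniquenesses are
#' floored at 0.005 to contain Heywood cases. Deterministic for a given
#' matrix.
#'
#' @param pm a [prepare_population_matrix()] result (or bare matrix).
#' @param n_factors number of common factors.
#' @return object of class `latent_model`: list with `loadings` (cells x
#'   factors), `scores` (rows x factors), `uniquenesses`, `n_factors`.
#' @export
fit_latent_model <- function(pm, n_factors = 10) {
  X <- if (inherits(pm, "population_matrix")) pm$X else pm
  if (nrow(X) <= ncol(X) / 2)
    stop("latent model: need more rows than half the number of cells")
  fa <- tryCatch(
    factanal(x = X, factors = n_factors, scores = "regression",
             rotation = "none", control = list(lower = 0.005)),
    error = function(e) stop("factor analysis did not converge: ",
                             conditionMessage(e)))
  structure(list(loadings = unclass(fa$loadings), scores = fa$scores,
                 uniquenesses = fa$uniquenesses, n_factors = n_factors,
                 converged = fa$converged),
            class = "latent_model")
}

# trial-averaged latent trajectory (bins x factors) for one epoch
epoch_trajectory <- function(model, pm, epoch) {
  sel <- pm$rows$epoch == epoch
  sc <- model$scores[sel, , drop = FALSE]
  bins <- pm$rows$bin[sel]
  agg <- rowsum(sc, bins) / as.vector(table(bins))
  list(bins = as.integer(rownames(agg)), traj = agg)
}

#' Latent trajectory divergence between epochs
#'
#' Euclidean distance in the full latent space between the trial-averaged
#' trajectories of two epochs, per spatial bin; the mean distance over the
#' ten bins preceding the stimulation zone is reported as the reference
#' level. Bins after the stimulation zone are tested with a cluster-based
#' trial permutation: the per-bin statistic is the trial-averaged
#' divergence of the stimulation epoch from the pre average minus the same
#' quantity for an unstimulated control epoch (baseline) *at the same
#' bin*; trial labels are permuted between the stimulation and control
#' groups (one permutation applies across all bins, so the spatial
#' correlation of the trajectories is carried into the null); bins
#' exceeding their own permutation 95th percentile form contiguous
#' clusters whose mass is referred to the permutation distribution of the
#' maximum cluster mass. Same-bin comparison keeps the test calibrated
#' when trajectory variability differs along the track (reward-dwell bins
#' vary with the mix of stop positions), the control arm cancels the
#' cross-epoch distance floor introduced by within-epoch z-scoring, and
#' the cluster statistic accounts for adjacent-bin dependence. When no
#' control epoch is present, a per-bin rank-sum of per-trial distances
#' against leave-one-out pre-epoch distances is reported with plain
#' run-length detection instead.
#'
#' @param model a [fit_latent_model()].
#' @param pm the matching [prepare_population_matrix()].
#' @param epoch_a,epoch_b compared epochs (default stimulation vs pre).
#' @param control_epoch unstimulated control arm for the per-bin test.
#' @param alpha per-bin (primary) significance level.
#' @param cluster_alpha cluster-level significance for `detected`.
#' @param min_run run length used by the fallback (no-control) detection.
#' @param n_perm trial permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `bins`, `distance`, `pre_bins`, `post_bins`, `p`
#'   (marginal per post-zone bin), `runs` (contiguous suprathreshold
#'   clusters with mass and cluster-level `p_cluster`), `detected`.
#' @export
trajectory_divergence <- function(model, pm, epoch_a = "stim",
                                  epoch_b = "pre",
                                  control_epoch = "baseline",
                                  alpha = 0.05, cluster_alpha = 0.05,
                                  min_run = 3, n_perm = 1000, seed = 1) {
  ta <- epoch_trajectory(model, pm, epoch_a)
  tb <- epoch_trajectory(model, pm, epoch_b)
  common <- intersect(ta$bins, tb$bins)
  d <- sqrt(rowSums((ta$traj[match(common, ta$bins), , drop = FALSE] -
                     tb$traj[match(common, tb$bins), , drop = FALSE])^2))
  zone <- pm$excluded_bins
  zone_lo <- if (length(zone)) min(zone)
    else position_bin(105, pm$bin_width) # fall back to the trigger bin
  zone_hi <- if (length(zone)) max(zone) else zone_lo
  pre_bins <- tail(common[common < zone_lo], 10)
  post_bins <- common[common > zone_hi]
  # per-trial scores by (trial, bin) for both epochs
  sel_a <- pm$rows$epoch == epoch_a
  sc_a <- model$scores[sel_a, , drop = FALSE]
  tr_a <- pm$rows$trial[sel_a]; bn_a <- pm$rows$bin[sel_a]
  sel_b <- pm$rows$epoch == epoch_b
  sc_b <- model$scores[sel_b, , drop = FALSE]
  tr_b <- pm$rows$trial[sel_b]; bn_b <- pm$rows$bin[sel_b]
  ref_a <- tb$traj[match(bn_a, tb$bins), , drop = FALSE]
  dt_a <- sqrt(rowSums((sc_a - ref_a)^2))
  use_ctrl <- !is.null(control_epoch) &&
    control_epoch %in% pm$rows$epoch
  set.seed(seed)
  if (use_ctrl) {
    sel_c <- pm$rows$epoch == control_epoch
    sc_c <- model$scores[sel_c, , drop = FALSE]
    bn_c <- pm$rows$bin[sel_c]
    tr_c <- pm$rows$trial[sel_c]
    # per-bin pooled scores with their trial ids
    pd <- lapply(post_bins, function(b) {
      ia <- which(bn_a == b); ic <- which(bn_c == b)
      list(S = rbind(sc_a[ia, , drop = FALSE], sc_c[ic, , drop = FALSE]),
           tr = c(tr_a[ia], tr_c[ic]),
           ref = tb$traj[match(b, tb$bins), ],
           ok = length(ia) >= 3 && length(ic) >= 3)
    })
    trials_a <- unique(tr_a[bn_a %in% post_bins])
    trials_c <- unique(tr_c[bn_c %in% post_bins])
    all_tr <- c(trials_a, trials_c)
    n1 <- length(trials_a)
    tstat <- function(group1) vapply(pd, function(x) {
      if (!x$ok) return(NA_real_)
      g1 <- x$tr %in% group1
      if (sum(g1) < 2 || sum(!g1) < 2) return(NA_real_)
      sqrt(sum((colMeans(x$S[g1, , drop = FALSE]) - x$ref)^2)) -
        sqrt(sum((colMeans(x$S[!g1, , drop = FALSE]) - x$ref)^2))
    }, numeric(1))
    obs <- tstat(trials_a)
    null_t <- vapply(seq_len(n_perm), function(k)
      tstat(sample(all_tr, n1)), numeric(length(post_bins)))
    if (is.null(dim(null_t))) null_t <- matrix(null_t, nrow = 1)
    q_hi <- apply(null_t, 1, quantile, probs = 1 - alpha, na.rm = TRUE)
    p <- vapply(seq_along(post_bins), function(j)
      if (is.na(obs[j])) NA_real_
      else (1 + sum(null_t[j, ] >= obs[j], na.rm = TRUE)) / (n_perm + 1),
      numeric(1))
    cluster_masses <- function(tvec) {
      over <- !is.na(tvec) & !is.na(q_hi) & tvec > q_hi
      r <- rle(over)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      keep <- which(r$values)
      list(starts = starts[keep], ends = ends[keep],
           mass = vapply(keep, function(k) {
             i <- starts[k]:ends[k]
             sum(tvec[i] - q_hi[i])
           }, numeric(1)))
    }
    ob_cl <- cluster_masses(obs)
    null_max <- vapply(seq_len(n_perm), function(k) {
      m <- cluster_masses(null_t[, k])$mass
      if (length(m)) max(m) else 0
    }, numeric(1))
    p_cl <- vapply(ob_cl$mass, function(m)
      (1 + sum(null_max >= m)) / (n_perm + 1), numeric(1))
    runs <- data.frame(from_bin = post_bins[ob_cl$starts],
                       to_bin = post_bins[ob_cl$ends],
                       length = ob_cl$ends - ob_cl$starts + 1,
                       mass = ob_cl$mass, p_cluster = p_cl)
    detected <- any(runs$p_cluster < cluster_alpha)
  } else {
    p <- vapply(post_bins, function(b) {
      ref <- tb$traj[match(b, tb$bins), ]
      sa <- sc_a[bn_a == b, , drop = FALSE]
      if (nrow(sa) < 3) return(NA_real_)
      da <- sqrt(rowSums((sa - rep(ref, each = nrow(sa)))^2))
      ib <- which(bn_b == b)
      nb_tr <- length(ib)
      if (nb_tr < 3) return(NA_real_)
      # leave-one-out distance of each epoch-b trial to the others' average
      mu <- colMeans(sc_b[ib, , drop = FALSE])
      dc <- vapply(ib, function(i) {
        loo <- (mu * nb_tr - sc_b[i, ]) / (nb_tr - 1)
        sqrt(sum((sc_b[i, ] - loo)^2))
      }, numeric(1))
      suppressWarnings(wilcox.test(da, dc, alternative = "greater")$p.value)
    }, numeric(1))
    sig <- !is.na(p) & p < alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    runs <- data.frame(from_bin = post_bins[starts[keep]],
                       to_bin = post_bins[ends[keep]],
                       length = r$lengths[keep],
                       mass = rep(NA_real_, length(keep)),
                       p_cluster = rep(NA_real_, length(keep)))
    detected <- any(runs$length >= min_run)
  }
  list(bins = common, distance = d, pre_bins = pre_bins,
       post_bins = post_bins, p = p, runs = runs, detected = detected)
}

#' Select cells eligible for perturbation scoring
#'
#' Keeps cells whose largest absolute factor loading is at least
#' `loading_min` and whose mean activity difference (stim - pre) over the
#' ten bins preceding the stimulation zone is at most
#' `pre_zone_diff_max` SDs in magnitude (cells already departing before
#' the stimulation zone are excluded).
#'
#' @param model a [fit_latent_model()].
#' @param pm the matching population matrix.
#' @param loading_min,pre_zone_diff_max thresholds.
#' @param epoch_a,epoch_b compared epochs.
#' @return logical vector over `pm$cell_ids`; pre-zone differences in
#'   attribute `"pre_zone_diff"`.
#' @export
select_analysis_cells <- function(model, pm, loading_min = 0.2,
                                  pre_zone_diff_max = 0.2,
                                  epoch_a = "stim", epoch_b = "pre") {
  max_load <- apply(abs(model$loadings), 1, max)
  zone_lo <- if (length(pm$excluded_bins)) min(pm$excluded_bins)
    else position_bin(105, pm$bin_width)
  pre_bins <- tail(sort(unique(pm$rows$bin[pm$rows$bin < zone_lo])), 10)
  dif <- cell_activity_difference(pm, pre_bins, epoch_a, epoch_b)
  keep <- max_load >= loading_min & abs(dif) <= pre_zone_diff_max &
    is.finite(dif)
  attr(keep, "pre_zone_diff") <- dif
  keep
}

# per-cell trial-averaged activity difference (epoch_a - epoch_b) over bins
cell_activity_difference <- function(pm, bins, epoch_a = "stim",
                                     epoch_b = "pre") {
  avg <- function(e) {
    sel <- pm$rows$epoch == e & pm$rows$bin %in% bins
    if (!any(sel)) return(rep(NA_real_, ncol(pm$X)))
    colMeans(pm$X[sel, , drop = FALSE])
  }
  avg(epoch_a) - avg(epoch_b)
}

#' Perturbation scores and suppressed/enhanced calling
#'
#' Each eligible cell's score is its trial-averaged activity difference
#' (stimulation minus pre epoch, SD units) averaged over three spatial
#' bins following the stimulation zone (centred at 136 cm). Cells below
#' the session's 10th percentile are `suppressed`, above the 90th
#' `enhanced`. The identical procedure applies to no-stimulation sessions
#' (epochs by experimental time) to build null distributions.
#'
#' @param pm a population matrix.
#' @param eligible logical from [select_analysis_cells()].
#' @param center_cm centre of the scoring window, cm.
#' @param n_zone_bins number of scoring bins.
#' @param epoch_a,epoch_b compared epochs.
#' @return data.frame `cell_id`, `score`, `class`.
#' @export
perturbation_scores <- function(pm, eligible, center_cm = 136,
                                n_zone_bins = 3, epoch_a = "stim",
                                epoch_b = "pre") {
  ids <- pm$cell_ids[eligible]
  if (length(ids) < 10)
    stop("perturbation_scores: need at least 10 eligible cells for deciles")
  cb <- position_bin(center_cm, pm$bin_width)
  half <- (n_zone_bins - 1) %/% 2
  zone_bins <- (cb - half):(cb - half + n_zone_bins - 1)
  dif <- cell_activity_difference(pm, zone_bins, epoch_a, epoch_b)[eligible]
  lo <- quantile(dif, 0.10, na.rm = TRUE)
  hi <- quantile(dif, 0.90, na.rm = TRUE)
  cls <- ifelse(dif < lo, "suppressed", ifelse(dif > hi, "enhanced", "neither"))
  data.frame(cell_id = ids, score = dif, class = cls,
             stringsAsFactors = FALSE)
}

#' Stimulus-triggered average traces
#'
#' Standardised (z-scored) dF/F aligned to stimulation onset, smoothed
#' with a Gaussian filter (default SD 5 imaging frames) and averaged over
#' trials.
#'
#' @param dff neurons x frames dF/F.
#' @param onsets onset frame indices (>= 3).
#' @param pre,post frames before/after onset.
#' @param smooth_sd_frames Gaussian smoothing SD, frames.
#' @return neurons x (pre+post) matrix; relative frames in attribute
#'   `"rel_frames"`.
#' @export
stim_triggered_average <- function(dff, onsets, pre = 30, post = 120,
                                   smooth_sd_frames = 5) {
  nf <- ncol(dff)
  ok <- onsets - pre >= 1 & onsets + post - 1 <= nf
  if (sum(ok) < length(onsets))
    warning("dropping ", sum(!ok), " onset(s) near the recording edge")
  onsets <- onsets[ok]
  if (length(onsets) < 3) stop("stim_triggered_average: need >= 3 onsets")
  z <- t(scale(t(dff)))
  z[!is.finite(z)] <- 0  # zero-variance cells have no standardised signal
  acc <- 0
  for (o in onsets) {
    seg <- z[, (o - pre):(o + post - 1), drop = FALSE]
    acc <- acc + smooth_bins(seg, smooth_sd_frames)
  }
  out <- acc / length(onsets)
  attr(out, "rel_frames") <- (-pre):(post - 1)
  out
}
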