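#' Occupancy-matched spatial downsampling
#'
#' Control analysis that equalises exploration between two recordings
#' before comparing spatial statistics. Each recording is reduced to a
#' per-tracking-sample list `L = (x_t, y_t, spike_t)` (position and the
#' number of spikes emitted in that sample interval; one tracking sample
#' is the time-bin granularity). Recording B is binned into `bin_size` cm
#' squares; A is binned with the same number of bins scaled to A's arena
#' extent. On every repetition, entries of A are drawn per bin with
#' replacement, the number drawn from each bin being the minimum of the
#' two recordings' counts in that bin, and the rate map and spatial
#' statistics are recomputed from the sampled entries.
#'
#' Downsampling a recording against itself is the calibration case: the
#' per-bin minima equal the original counts, occupancy is unchanged, and
#' only the resampling noise perturbs the statistics. Spatial coherence is
#' expected to resist this perturbation better than spatial information or
#' sparsity.
#'
#' @param track_a,spikes_a Recording A (the one being downsampled).
#' @param track_b,spikes_b Recording B (the exploration target). Defaults
#'   to recording A (self-downsampling).
#' @param bin_size Spatial bin side for B, cm (default 3).
#' @param n_reps Number of repetitions (default 200).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `downsample_result`: `n_reps`,
#'   `coherence_per_rep`, `info_per_rep`, `sparsity_per_rep`, their means
#'   (`mean_coherence`, ...), `mean_decrease_vs_original` (original
#'   coherence minus mean resampled coherence), `original` (list of the
#'   undownsampled coherence/information/sparsity at the matched binning)
#'   and `per_bin_target` (the per-bin sample counts used).
#' @export
spatial_downsample <- function(track_a, spikes_a, track_b = track_a,
                               spikes_b = spikes_a, bin_size = 3,
                               n_reps = 200, seed = NULL) {
  stopifnot(inherits(track_a, "position_track"),
            inherits(spikes_a, "spike_train"))
  if (!is.null(seed)) set.seed(seed)
  # bin counts from B, reused for A scaled to A's arena extent
  nx <- n_bins(track_b$arena$width, bin_size)
  ny <- n_bins(track_b$arena$height, bin_size)
  la <- sample_list(track_a, spikes_a)
  lb <- sample_list(track_b, spikes_b)
  bin_a <- scaled_bin(la, track_a$arena, nx, ny)
  bin_b <- scaled_bin(lb, track_b$arena, nx, ny)
  cnt_a <- tabulate(bin_a, nbins = nx * ny)
  cnt_b <- tabulate(bin_b, nbins = nx * ny)
  target <- pmin(cnt_a, cnt_b)
  if (all(target == 0))
    stop("recordings have disjoint occupancy; nothing to sample")
  dt <- 1 / track_a$rate_hz
  occ <- matrix(target * dt, nx, ny)
  by_bin <- split(seq_along(bin_a), bin_a)
  active <- names(by_bin)[target[as.integer(names(by_bin))] > 0]
  # original (undownsampled) statistics of A at this binning
  occ_a <- matrix(cnt_a * dt, nx, ny)
  cnt_spk_a <- matrix(0, nx, ny)
  acc <- rowsum(la$spk, bin_a)
  cnt_spk_a[as.integer(rownames(acc))] <- acc
  orig_map <- new_rate_map(occ_a, cnt_spk_a, bin_size, track_a$arena)
  original <- list(coherence = spatial_coherence(orig_map),
                   information = spatial_information(orig_map),
                   sparsity = sparsity(orig_map))
  coh <- info <- spars <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    idx <- unlist(lapply(active, function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), target[as.integer(b)],
                      replace = TRUE)]
    }), use.names = FALSE)
    spk <- matrix(0, nx, ny)
    acc <- rowsum(la$spk[idx], bin_a[idx])
    spk[as.integer(rownames(acc))] <- acc
    m <- new_rate_map(occ, spk, bin_size, track_a$arena)
    coh[rep] <- spatial_coherence(m)
    info[rep] <- spatial_information(m)
    spars[rep] <- sparsity(m)
  }
  structure(list(n_reps = n_reps,
                 coherence_per_rep = coh,
                 info_per_rep = info,
                 sparsity_per_rep = spars,
                 mean_coherence = mean(coh, na.rm = TRUE),
                 mean_information = mean(info, na.rm = TRUE),
                 mean_sparsity = mean(spars, na.rm = TRUE),
                 mean_decrease_vs_original =
                   original$coherence - mean(coh, na.rm = TRUE),
                 original = original,
                 per_bin_target = matrix(target, nx, ny)),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf(paste0("<downsample_result: %d reps, mean coherence %.3f ",
                     "(original %.3f)>\n"),
              x$n_reps, x$mean_coherence, x$original$coherence))
  invisible(x)
}

# Per-sample list L = (x, y, spikes in the sample interval).
sample_list <- function(track, spikes) {
  fi <- pmin(pmax(findInterval(spikes$times, track$t), 1L),
             length(track$t))
  list(x = track$x, y = track$y,
       spk = tabulate(fi, nbins = length(track$t)))
}

# Bin sample positions on an nx x ny grid spanning the arena extent.
scaled_bin <- function(l, arena, nx, ny) {
  bx <- pmin(pmax(as.integer(floor(l$x / (arena$width / nx))) + 1L, 1L), nx)
  by <- pmin(pmax(as.integer(floor(l$y / (arena$height / ny))) + 1L, 1L), ny)
  (by - 1L) * nx + bx
}

# Minimal rate-map object from occupancy and spike-count matrices; used by
# the downsampling loop where track interpolation is not needed.
new_rate_map <- function(occ, cnt, bin_size, arena, smoothing_sigma = 0) {
  visited <- occ > 0
  rate <- matrix(NA_real_, nrow(occ), ncol(occ))
  rate[visited] <- cnt[visited] / occ[visited]
  rs <- if (smoothing_sigma > 0)
    gauss_smooth_masked(rate, visited, smoothing_sigma) else rate
  structure(list(occupancy = occ, spike_count = cnt, rate = rate,
                 rate_smooth = rs, visited = visited,
                 nx = nrow(occ), ny = ncol(occ), bin_size = bin_size,
                 arena = arena, duration = sum(occ), n_spikes = sum(cnt)),
            class = "rate_map")
}

#' Symmetric occupancy-matched coherence pair
#'
#' Cross-matches two recordings: the baseline is downsampled to match the
#' treatment's exploration and the treatment is downsampled to match the
#' baseline's, yielding two coherence estimates on closely matching
#' occupancy.
#'
#' @param track_base,spikes_base Baseline recording.
#' @param track_treat,spikes_treat Treatment recording.
#' @inheritParams spatial_downsample
#' @return List with `coh_baseline_matched`, `coh_treatment_matched`
#'   (mean coherences over repetitions) and the two full
#'   [spatial_downsample()] results (`baseline`, `treatment`).
#' @export
matched_coherence_pair <- function(track_base, spikes_base, track_treat,
                                   spikes_treat, bin_size = 3,
                                   n_reps = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- spatial_downsample(track_base, spikes_base, track_treat,
                          spikes_treat, bin_size, n_reps, seed = NULL)
  b <- spatial_downsample(track_treat, spikes_treat, track_base,
                          spikes_base, bin_size, n_reps, seed = NULL)
  list(coh_baseline_matched = a$mean_coherence,
       coh_treatment_matched = b$mean_coherence,
       baseline = a, treatment = b)
}
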