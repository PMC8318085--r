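#' Skaggs spatial information content
#'
#' Information carried by a single spike about the animal's location, in
#' bits per spike:
#' \deqn{I = \sum_i p_i \frac{\lambda_i}{\bar\lambda}
#'   \log_2 \frac{\lambda_i}{\bar\lambda}}
#' where \eqn{p_i} is the occupancy probability of pixel i,
#' \eqn{\lambda_i} its firing rate, and
#' \eqn{\bar\lambda = \sum_i p_i \lambda_i} the occupancy-weighted mean
#' rate. The sum runs over visited pixels of the raw (unsmoothed) map and
#' \eqn{0 \log 0 \equiv 0}.
#'
#' @param map A [compute_ratemap()] result.
#' @return Bits per spike (non-negative up to float tolerance), or
#'   `NA_real_` if the mean rate is zero (an information content is then
#'   undefined, which is distinct from zero).
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  v <- map$visited
  occ <- map$occupancy[v]
  if (!length(occ) || sum(occ) <= 0) return(NA_real_)
  p <- occ / sum(occ)
  lam <- map$rate[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  pos <- lam > 0
  sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
}

#' Spatial coherence
#'
#' First-order spatial autocorrelation of the raw rate map: the Pearson
#' correlation between each visited pixel's rate and the mean rate of its
#' visited 8-neighbours. Pixels without any visited neighbour are
#' excluded. A smooth, reliable place field yields high coherence; the
#' place-cell criterion is coherence > 0.25.
#'
#' @param map A [compute_ratemap()] result.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined (fewer
#'   than two usable pixels, or zero variance on either side).
#' @export
spatial_coherence <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  r <- map$rate
  v <- map$visited
  nx <- map$nx; ny <- map$ny
  num <- matrix(0, nx, ny)
  den <- matrix(0, nx, ny)
  r0 <- ifelse(v, r, 0)
  k0 <- v + 0
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    num[xs, ys] <- num[xs, ys] + r0[xs + dx, ys + dy]
    den[xs, ys] <- den[xs, ys] + k0[xs + dx, ys + dy]
  }
  ok <- v & den > 0
  if (sum(ok) < 2L) return(NA_real_)
  a <- r[ok]
  b <- num[ok] / den[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Spatial sparsity
#'
#' Skaggs sparsity, \eqn{(\sum_i p_i \lambda_i)^2 / \sum_i p_i
#' \lambda_i^2}, over visited pixels of the raw map: roughly the fraction
#' of the environment in which the unit is active (1 for uniform firing,
#' 1/N for firing confined to one of N equally occupied pixels).
#'
#' @param map A [compute_ratemap()] result.
#' @return Sparsity in `(0, 1]`, or `NA_real_` for a zero-rate map.
#' @export
sparsity <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  v <- map$visited
  occ <- map$occupancy[v]
  if (!length(occ) || sum(occ) <= 0) return(NA_real_)
  p <- occ / sum(occ)
  lam <- map$rate[v]
  m1 <- sum(p * lam)
  m2 <- sum(p * lam^2)
  if (m2 <= 0) return(NA_real_)
  m1^2 / m2
}

#' Mean firing rate
#'
#' Total number of spikes divided by the total recording time, in
#' spikes/s.
#'
#' @param spikes A [spike_train()].
#' @return Rate in Hz.
#' @export
mean_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  if (spikes$duration <= 0) stop("spike train has zero duration")
  length(spikes$times) / spikes$duration
}

#' All scalar spatial metrics of one unit
#'
#' Convenience wrapper collecting [spatial_information()],
#' [spatial_coherence()], [sparsity()] and [mean_rate()]. Undefined
#' metrics propagate as `NA`, never as 0, so they cannot silently satisfy
#' or fail a classification threshold.
#'
#' @param map A [compute_ratemap()] result.
#' @param spikes The [spike_train()] the map was built from.
#' @return A list of class `spatial_metrics` with fields
#'   `info_bits_per_spike`, `coherence`, `sparsity`, `mean_rate`.
#' @export
spatial_metrics <- function(map, spikes) {
  structure(list(info_bits_per_spike = spatial_information(map),
                 coherence = spatial_coherence(map),
                 sparsity = sparsity(map),
                 mean_rate = mean_rate(spikes)),
            class = "spatial_metrics")
}

#' @export
print.spatial_metrics <- function(x, ...) {
  cat(sprintf(paste0("<spatial_metrics: %.3f bits/spike, coherence %.3f, ",
                     "sparsity %.3f, %.3f Hz>\n"),
              x$info_bits_per_spike, x$coherence, x$sparsity, x$mean_rate))
  invisible(x)
}
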