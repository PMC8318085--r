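#' Occupancy-normalised firing rate map
#'
#' Bins the arena into `bin_size` cm square pixels, accumulates the time
#' spent and the number of spikes per pixel, and forms the firing rate
#' `rate = spike_count / occupancy` on visited pixels. Spike positions are
#' obtained by linear interpolation of the track at each spike time.
#' Pixels never visited are masked (`NA` rate).
#'
#' A Gaussian-smoothed copy of the rate (`rate_smooth`, mask-aware kernel
#' of width `smoothing_sigma` bins) is carried alongside for display and
#' field detection; the scalar spatial metrics are computed on the raw
#' map, where the first-order coherence statistic remains meaningful.
#'
#' Binning uses half-open intervals `[edge, edge + bin)` with the final
#' bin closed, so membership at the arena edge is unambiguous.
#'
#' @param track A [position_track()].
#' @param spikes A [spike_train()] sharing the track's time base.
#' @param bin_size Pixel side, cm (default 3).
#' @param smoothing_sigma Gaussian kernel sigma in bins for the smoothed
#'   copy; `0` disables smoothing.
#' @return An object of class `rate_map` with fields `occupancy` (s),
#'   `spike_count`, `rate` (Hz, raw), `rate_smooth` (Hz), `visited`
#'   (logical), `nx`, `ny`, `bin_size`, `arena`, `duration`, `n_spikes`.
#' @export
compute_ratemap <- function(track, spikes, bin_size = 3,
                            smoothing_sigma = 1) {
  stopifnot(inherits(track, "position_track"),
            inherits(spikes, "spike_train"), bin_size > 0)
  dur <- track_duration(track)
  if (dur <= 0) stop("track has zero duration")
  nx <- n_bins(track$arena$width, bin_size)
  ny <- n_bins(track$arena$height, bin_size)
  dt <- c(diff(track$t), 1 / track$rate_hz)
  ix <- bin_index(track$x, bin_size, nx)
  iy <- bin_index(track$y, bin_size, ny)
  cell <- (iy - 1L) * nx + ix
  occ <- matrix(0, nx, ny)
  acc <- rowsum(dt, cell)
  occ[as.integer(rownames(acc))] <- acc
  sx <- stats::approx(track$t, track$x, spikes$times, rule = 2)$y
  sy <- stats::approx(track$t, track$y, spikes$times, rule = 2)$y
  cnt <- matrix(0, nx, ny)
  if (length(sx)) {
    scell <- (bin_index(sy, bin_size, ny) - 1L) * nx +
      bin_index(sx, bin_size, nx)
    cnt[] <- tabulate(scell, nbins = nx * ny)
  }
  visited <- occ > 0
  rate <- matrix(NA_real_, nx, ny)
  rate[visited] <- cnt[visited] / occ[visited]
  rs <- if (smoothing_sigma > 0)
    gauss_smooth_masked(rate, visited, smoothing_sigma) else rate
  structure(list(occupancy = occ, spike_count = cnt, rate = rate,
                 rate_smooth = rs, visited = visited, nx = nx, ny = ny,
                 bin_size = bin_size, arena = track$arena,
                 duration = dur, n_spikes = length(spikes$times)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate_map: %d x %d pixels of %g cm, %.0f%% visited, %d spikes>\n",
    x$nx, x$ny, x$bin_size, 100 * mean(x$visited), x$n_spikes))
  invisible(x)
}

# Number of bins covering an extent; a partial trailing bin counts.
n_bins <- function(extent, bin_size) {
  as.integer(ceiling(extent / bin_size - 1e-9))
}

# Half-open binning [edge, edge + bin), final bin closed.
bin_index <- function(v, bin_size, nb) {
  pmin(pmax(as.integer(floor(v / bin_size)) + 1L, 1L), nb)
}

# Mask-aware Gaussian smoothing: kernel-weighted mean over visited pixels
# within a 3-sigma radius; unvisited pixels stay NA.
gauss_smooth_masked <- function(m, mask, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  nx <- nrow(m); ny <- ncol(m)
  num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
  m0 <- ifelse(mask, m, 0)
  k0 <- mask + 0
  for (dx in -r:r) for (dy in -r:r) {
    w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    num[xs, ys] <- num[xs, ys] + w * m0[xs + dx, ys + dy]
    den[xs, ys] <- den[xs, ys] + w * k0[xs + dx, ys + dy]
  }
  out <- matrix(NA_real_, nx, ny)
  out[mask] <- num[mask] / den[mask]
  out
}

#' Arena coverage of a track
#'
#' Fraction of arena pixels visited at least once (one tracking sample is
#' enough to count as visited). Session-inclusion analyses require
#' coverage of at least 0.90. The per-pixel number of visits (entries into
#' the pixel) is attached as attribute `"visits"` for exploration checks
#' that compare occupancy against visit counts.
#'
#' @param track A [position_track()].
#' @param bin_size Pixel side, cm.
#' @return Fraction in `[0, 1]` with attribute `visits` (an
#'   `nx` x `ny` integer matrix).
#' @export
coverage <- function(track, bin_size = 3) {
  stopifnot(inherits(track, "position_track"))
  nx <- n_bins(track$arena$width, bin_size)
  ny <- n_bins(track$arena$height, bin_size)
  cell <- (bin_index(track$y, bin_size, ny) - 1L) * nx +
    bin_index(track$x, bin_size, nx)
  entries <- cell[c(TRUE, diff(cell) != 0)]
  visits <- matrix(tabulate(entries, nbins = nx * ny), nx, ny)
  frac <- mean(visits > 0)
  attr(frac, "visits") <- visits
  frac
}

#' Detect firing fields and place fields
#'
#' A firing field is a set of at least nine contiguous pixels (sharing a
#' side, i.e. 4-connectivity) with firing rate above zero. A place field
#' additionally requires its pixels to exceed 20 % of the map's peak
#' rate. Detection runs on the smoothed rate when available.
#'
#' @param map A [compute_ratemap()] result.
#' @param min_pixels Minimum field size in pixels (default 9).
#' @return An object of class `field_set`: list with `fields` (list of
#'   integer pixel-index vectors into the map matrix), `sizes` (pixel
#'   counts) and `peak_rate` (Hz, map peak).
#' @export
detect_firing_fields <- function(map, min_pixels = 9L) {
  r <- field_rate(map)
  field_set_from_mask(!is.na(r) & r > 0, r, map, min_pixels)
}

#' @rdname detect_firing_fields
#' @param threshold Fraction of the peak rate a place-field pixel must
#'   exceed (default 0.2).
#' @export
detect_place_fields <- function(map, min_pixels = 9L, threshold = 0.2) {
  r <- field_rate(map)
  peak <- suppressWarnings(max(r, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0)
    return(structure(list(fields = list(), sizes = integer(0),
                          peak_rate = 0, nx = map$nx, ny = map$ny),
                     class = "field_set"))
  field_set_from_mask(!is.na(r) & r > threshold * peak, r, map, min_pixels)
}

field_rate <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (is.null(map$rate_smooth)) map$rate else map$rate_smooth
}

field_set_from_mask <- function(mask, r, map, min_pixels) {
  comps <- label_components(mask)
  comps <- comps[lengths(comps) >= min_pixels]
  peak <- suppressWarnings(max(r, na.rm = TRUE))
  structure(list(fields = comps, sizes = lengths(comps),
                 peak_rate = if (is.finite(peak)) peak else 0,
                 nx = map$nx, ny = map$ny),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set: %d field(s)%s, peak %.2f Hz>\n",
              length(x$fields),
              if (length(x$sizes))
                paste0(" of ", paste(x$sizes, collapse = ", "), " px")
              else "", x$peak_rate))
  invisible(x)
}

# 4-connected components of a logical matrix, via a graph of side-sharing
# pixel pairs. Returns a list of integer index vectors (column-major).
label_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nx <- nrow(mask); ny <- ncol(mask)
  # pairs sharing a vertical side (neighbour in x)
  a <- which(mask[-nx, , drop = FALSE] & mask[-1, , drop = FALSE])
  r <- (a - 1L) %% (nx - 1L) + 1L; cc <- (a - 1L) %/% (nx - 1L) + 1L
  e1 <- (cc - 1L) * nx + r
  # pairs sharing a horizontal side (neighbour in y)
  b <- which(mask[, -ny, drop = FALSE] & mask[, -1, drop = FALSE])
  r2 <- (b - 1L) %% nx + 1L; c2 <- (b - 1L) %/% nx + 1L
  f1 <- (c2 - 1L) * nx + r2
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(e1) + length(f1) > 0) {
    el <- rbind(cbind(match(e1, idx), match(e1 + 1L, idx)),
                cbind(match(f1, idx), match(f1 + nx, idx)))
    g <- igraph::add_edges(g, t(el))
  }
  memb <- igraph::components(g)$membership
  unname(split(idx, memb))
}

#' Export a rate map as a TSV matrix
#'
#' Writes the (smoothed, if available) rate matrix with x bins as rows and
#' y bins as columns; unvisited pixels are written as `NA`.
#'
#' @param map A [compute_ratemap()] result.
#' @param path Output path.
#' @param smoothed Write the smoothed (`TRUE`, default) or raw rate.
#' @return `path`, invisibly.
#' @export
write_ratemap <- function(map, path, smoothed = TRUE) {
  r <- if (smoothed) field_rate(map) else map$rate
  utils::write.table(r, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
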