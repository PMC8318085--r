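#' Head-direction tuning curve
#'
#' Firing rate as a function of head direction in fixed-width bins
#' (default 5 degrees, i.e. 72 bins): spikes falling in each heading bin
#' divided by the time spent facing that bin. Dwell time is accumulated
#' from the sample intervals assigned to the heading bin of each tracking
#' sample; each spike takes the heading of the nearest preceding sample.
#' Bins with zero dwell are masked and excluded from the resultant.
#'
#' The mean resultant of the rate-weighted bin centres summarises tuning
#' strength (`resultant_length` in `[0, 1]`) and preferred direction.
#'
#' @param track A [position_track()] with heading.
#' @param spikes A [spike_train()].
#' @param bin_width Bin width in degrees; must divide 360.
#' @return An object of class `hd_tuning`: `bin_width`, `bin_centers`
#'   (degrees), `dwell` (s), `spike_count`, `bin_rate` (Hz, `NA` where
#'   dwell is zero), `resultant_length`, `preferred_direction` (degrees).
#' @export
hd_tuning <- function(track, spikes, bin_width = 5) {
  stopifnot(inherits(track, "position_track"),
            inherits(spikes, "spike_train"))
  nb <- round(360 / bin_width)
  if (abs(nb * bin_width - 360) > 1e-9)
    stop("bin_width must divide 360 degrees")
  dt <- c(diff(track$t), 1 / track$rate_hz)
  hb <- pmin(as.integer(floor(track$heading / bin_width)) + 1L, nb)
  dwell <- numeric(nb)
  acc <- rowsum(dt, hb)
  dwell[as.integer(rownames(acc))] <- acc
  is <- pmin(pmax(findInterval(spikes$times, track$t), 1L), length(track$t))
  sh <- track$heading[is]
  cnt <- tabulate(pmin(as.integer(floor(sh / bin_width)) + 1L, nb),
                  nbins = nb)
  rate <- ifelse(dwell > 0, cnt / dwell, NA_real_)
  centers <- (seq_len(nb) - 0.5) * bin_width
  ok <- dwell > 0
  w <- rate[ok]
  th <- centers[ok] * pi / 180
  if (!any(ok) || sum(w) <= 0) {
    rl <- NA_real_; pref <- NA_real_
  } else {
    cx <- sum(w * cos(th)); cy <- sum(w * sin(th))
    rl <- sqrt(cx^2 + cy^2) / sum(w)
    pref <- (atan2(cy, cx) * 180 / pi) %% 360
  }
  structure(list(bin_width = bin_width, bin_centers = centers,
                 dwell = dwell, spike_count = cnt, bin_rate = rate,
                 resultant_length = rl, preferred_direction = pref),
            class = "hd_tuning")
}

#' @export
print.hd_tuning <- function(x, ...) {
  cat(sprintf("<hd_tuning: %d bins of %g deg, resultant %.3f at %.1f deg>\n",
              length(x$bin_centers), x$bin_width,
              x$resultant_length, x$preferred_direction))
  invisible(x)
}

#' 2-D spatial autocorrelation of a rate map
#'
#' Pearson correlation of the map with itself at every integer-pixel lag,
#' computed over the pixels where both copies are visited. Lags with
#' fewer than `min_overlap` overlapping pixels are masked. The smoothed
#' rate is used when available (grid structure is assessed on smoothed
#' maps); the result is point-symmetric and equals 1 at zero lag.
#'
#' @param map A [compute_ratemap()] result.
#' @param min_overlap Minimum overlapping pixels per lag (default 20).
#' @return An object of class `autocorrelogram`: `values` (matrix over
#'   lags, `NA` where masked), `lags_x`, `lags_y` (in pixels), `lag_size`
#'   (cm per pixel), `min_overlap`.
#' @export
spatial_autocorrelation <- function(map, min_overlap = 20) {
  stopifnot(inherits(map, "rate_map"))
  r <- field_rate(map)
  r[!map$visited] <- NA
  nx <- map$nx; ny <- map$ny
  lx <- -(nx - 1L):(nx - 1L)
  ly <- -(ny - 1L):(ny - 1L)
  vals <- matrix(NA_real_, length(lx), length(ly))
  for (b in seq_along(ly)) {
    dy <- ly[b]
    if (dy < 0) next  # fill by point symmetry afterwards
    for (a in seq_along(lx)) {
      dx <- lx[a]
      if (dy == 0 && dx < 0) next
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      v1 <- r[xs, ys]
      v2 <- r[xs - dx, ys - dy]
      ok <- !is.na(v1) & !is.na(v2)
      if (sum(ok) < min_overlap) next
      a1 <- v1[ok]; a2 <- v2[ok]
      s1 <- stats::sd(a1); s2 <- stats::sd(a2)
      if (s1 == 0 || s2 == 0) next
      vals[a, b] <- stats::cor(a1, a2)
    }
  }
  # point symmetry: values(-tau) = values(tau)
  full <- vals
  for (b in seq_along(ly)) for (a in seq_along(lx)) {
    if (is.na(full[a, b]))
      full[a, b] <- vals[length(lx) + 1L - a, length(ly) + 1L - b]
  }
  structure(list(values = full, lags_x = lx, lags_y = ly,
                 lag_size = map$bin_size, min_overlap = min_overlap),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram: %d x %d lags of %g cm>\n",
              length(x$lags_x), length(x$lags_y), x$lag_size))
  invisible(x)
}

#' Grid score, spacing and orientation
#'
#' Quantifies hexagonal periodicity from the spatial autocorrelogram. The
#' annulus between the central peak and 1.25 x the estimated spacing is
#' correlated with itself rotated by 30/60/90/120/150 degrees; the score
#' is `min(r60, r120) - max(r30, r90, r150)`, positive when the 60-degree
#' rotational symmetry of a triangular lattice dominates. Spacing is the
#' median distance of the six innermost autocorrelogram peaks and
#' orientation the angle of the lowest-angle peak modulo 60.
#'
#' The central-peak radius is the first local minimum of the radial
#' autocorrelation profile. If fewer than six peaks are found, spacing and
#' orientation are `NA` but a score is still returned, using the available
#' peaks (or half the maximal lag) to bound the annulus.
#'
#' @param ac An [spatial_autocorrelation()] result.
#' @return An object of class `grid_stats`: `grid_score`, `spacing` (cm),
#'   `orientation` (degrees in `[0, 60)`), `rotations` (named correlation
#'   vector), `n_peaks`.
#' @export
grid_score <- function(ac) {
  stopifnot(inherits(ac, "autocorrelogram"))
  v <- ac$values
  cx <- which(ac$lags_x == 0L)
  cy <- which(ac$lags_y == 0L)
  dxm <- matrix(ac$lags_x, length(ac$lags_x), length(ac$lags_y))
  dym <- matrix(ac$lags_y, length(ac$lags_x), length(ac$lags_y),
                byrow = TRUE)
  D <- sqrt(dxm^2 + dym^2)
  # radial profile and central-peak radius
  rr <- round(D)
  prof <- tapply(v[!is.na(v)], rr[!is.na(v)], mean)
  pr <- as.numeric(names(prof))
  o <- order(pr); pr <- pr[o]; prof <- as.numeric(prof)[o]
  r0 <- NA_real_
  if (length(prof) >= 3L) {
    for (i in 2:(length(prof) - 1L)) {
      if (prof[i] < prof[i - 1L] && prof[i] <= prof[i + 1L]) {
        r0 <- pr[i]; break
      }
    }
  }
  if (is.na(r0)) r0 <- pr[which(prof < 0)[1L]]
  if (is.na(r0)) r0 <- max(D) / 4
  # peaks: local maxima over the 8-neighbourhood, outside the central peak
  pk <- find_local_maxima(v)
  pk <- pk[D[pk] > r0 & v[pk] > 0]
  pk <- pk[order(D[pk])]
  n_peaks <- min(length(pk), 6L)
  spacing <- NA_real_; orientation <- NA_real_
  if (n_peaks > 0L) {
    six <- pk[seq_len(n_peaks)]
    med <- stats::median(D[six])
    if (n_peaks == 6L) {
      spacing <- med * ac$lag_size
      ang <- (atan2(dym[six], dxm[six]) * 180 / pi) %% 360
      orientation <- min(ang %% 60)
    }
    outer_r <- 1.25 * med
  } else {
    outer_r <- max(D) / 2
  }
  # keep the annulus inside the reliably estimated lag range (corner lags
  # have little overlap) and guarantee a non-degenerate annulus
  outer_r <- min(outer_r, 0.75 * max(ac$lags_x), 0.75 * max(ac$lags_y))
  r0 <- min(r0, 0.6 * outer_r)
  ann <- which(D > r0 & D <= outer_r & !is.na(v))
  rots <- c(r30 = NA_real_, r60 = NA_real_, r90 = NA_real_,
            r120 = NA_real_, r150 = NA_real_)
  if (length(ann) >= 10L) {
    angles <- c(30, 60, 90, 120, 150)
    for (j in seq_along(angles)) {
      th <- angles[j] * pi / 180
      rx <- dxm[ann] * cos(th) - dym[ann] * sin(th)
      ry <- dxm[ann] * sin(th) + dym[ann] * cos(th)
      w <- bilinear_at(v, ac$lags_x, ac$lags_y, rx, ry)
      ok <- !is.na(w)
      if (sum(ok) >= 10L && stats::sd(v[ann][ok]) > 0 &&
          stats::sd(w[ok]) > 0)
        rots[j] <- stats::cor(v[ann][ok], w[ok])
    }
  }
  score <- if (anyNA(rots)) NA_real_ else
    min(rots["r60"], rots["r120"]) -
      max(rots["r30"], rots["r90"], rots["r150"])
  structure(list(grid_score = unname(score), spacing = spacing,
                 orientation = orientation, rotations = rots,
                 n_peaks = n_peaks, central_radius = r0 * ac$lag_size),
            class = "grid_stats")
}

#' @export
print.grid_stats <- function(x, ...) {
  cat(sprintf("<grid_stats: score %.3f, spacing %.1f cm, orientation %.1f deg>\n",
              x$grid_score, x$spacing, x$orientation))
  invisible(x)
}

# Indices of strict-or-equal local maxima over the 8-neighbourhood,
# requiring the pixel to be >= all neighbours and > at least one.
find_local_maxima <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  best <- matrix(-Inf, nx, ny)
  m0 <- ifelse(is.na(m), -Inf, m)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    best[xs, ys] <- pmax(best[xs, ys], m0[xs + dx, ys + dy])
  }
  which(!is.na(m) & m0 >= best & is.finite(best))
}

# Bilinear interpolation of matrix values at fractional lag coordinates;
# NA if any of the four surrounding pixels is NA or out of range.
bilinear_at <- function(v, lags_x, lags_y, qx, qy) {
  fx <- qx - lags_x[1L] + 1
  fy <- qy - lags_y[1L] + 1
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  nx <- length(lags_x); ny <- length(lags_y)
  out <- rep(NA_real_, length(qx))
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  if (!any(ok)) return(out)
  i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  out[ok] <- (1 - wx[ok]) * (1 - wy[ok]) * v[i00] +
    wx[ok] * (1 - wy[ok]) * v[i10] +
    (1 - wx[ok]) * wy[ok] * v[i01] +
    wx[ok] * wy[ok] * v[i11]
  out
}

#' Border score of a rate map
#'
#' Quantifies firing concentrated along one arena wall, in the style of
#' the coverage-vs-distance construction: `c` is the maximum, over the
#' four walls, of the fraction of that wall's adjacent pixels covered by a
#' single field; `d` is the firing-rate-weighted mean distance of all
#' field pixels to their nearest wall, normalised by half the arena's
#' shorter side; the score is `(c - d) / (c + d)` in `[-1, 1]`.
#'
#' @param map A [compute_ratemap()] result.
#' @param fields A [detect_firing_fields()] result for the map.
#' @return An object of class `border_stats`: `wall_coverage`,
#'   `mean_field_distance_to_wall` (both in `[0, 1]`), `border_score`;
#'   all `NA` when there are no fields.
#' @export
border_score <- function(map, fields) {
  stopifnot(inherits(map, "rate_map"), inherits(fields, "field_set"))
  if (!length(fields$fields))
    return(structure(list(wall_coverage = NA_real_,
                          mean_field_distance_to_wall = NA_real_,
                          border_score = NA_real_),
                     class = "border_stats"))
  nx <- map$nx; ny <- map$ny
  wall_pix <- list(W = which(row(matrix(0, nx, ny)) == 1L),
                   E = which(row(matrix(0, nx, ny)) == nx),
                   S = which(col(matrix(0, nx, ny)) == 1L),
                   N = which(col(matrix(0, nx, ny)) == ny))
  cmax <- 0
  for (f in fields$fields)
    for (wp in wall_pix)
      cmax <- max(cmax, length(intersect(f, wp)) / length(wp))
  pix <- unlist(fields$fields)
  ix <- (pix - 1L) %% nx + 1L
  iy <- (pix - 1L) %/% nx + 1L
  xc <- (ix - 0.5) * map$bin_size
  yc <- (iy - 0.5) * map$bin_size
  dwall <- pmin(xc, map$arena$width - xc, yc, map$arena$height - yc)
  w <- field_rate(map)[pix]
  w[is.na(w) | w < 0] <- 0
  d <- if (sum(w) > 0) sum(w * dwall) / sum(w) else mean(dwall)
  d <- d / (min(map$arena$width, map$arena$height) / 2)
  structure(list(wall_coverage = cmax,
                 mean_field_distance_to_wall = d,
                 border_score = (cmax - d) / (cmax + d)),
            class = "border_stats")
}

#' @export
print.border_stats <- function(x, ...) {
  cat(sprintf("<border_stats: coverage %.2f, distance %.2f, score %.3f>\n",
              x$wall_coverage, x$mean_field_distance_to_wall,
              x$border_score))
  invisible(x)
}
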