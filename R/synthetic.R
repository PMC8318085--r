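#' Tuning specification for a synthetic unit
#'
#' Parameterises the firing-rate model of a simulated cell. Only the
#' fields relevant to `kind` are used; the rest are ignored.
#'
#' Tuning models (all rates in Hz):
#' * `place`: baseline + (peak - baseline) * Gaussian bump of width
#'   `place_sigma` around `place_center`.
#' * `grid`: baseline + (peak - baseline) * rectified sum of three
#'   plane-wave cosines at 60 degree separations, spacing `grid_spacing`,
#'   rotated by `grid_orientation`, translated by `grid_phase`.
#' * `hd`: baseline + (peak - baseline) * von Mises tuning of the head
#'   direction around `hd_preferred` with concentration `hd_kappa`,
#'   normalised to peak 1.
#' * `border`: baseline + (peak - baseline) * exp(-d/`border_sigma`) where
#'   d is the distance to the wall named by `border_wall`.
#' * `nonspatial`: constant `baseline_rate`.
#'
#' Defaults are chosen so that default cells clear the classification
#' criteria with margin: place sigma 8 cm, peak 5 Hz, baseline 0.1 Hz,
#' grid spacing 35 cm, hd kappa 4, border sigma 6 cm.
#'
#' @param kind One of `"place"`, `"grid"`, `"hd"`, `"border"`,
#'   `"nonspatial"`.
#' @param baseline_rate,peak_rate Baseline and peak firing rate, Hz;
#'   `peak_rate >= baseline_rate >= 0`.
#' @param place_center Length-2 cm pair; field centre.
#' @param place_sigma Gaussian field width, cm.
#' @param grid_spacing Distance between neighbouring grid vertices, cm.
#' @param grid_orientation Lattice orientation, degrees.
#' @param grid_phase Length-2 cm pair; lattice translation.
#' @param hd_preferred Preferred head direction, degrees.
#' @param hd_kappa von Mises concentration (dimensionless).
#' @param border_wall One of `"N"`, `"S"`, `"E"`, `"W"`.
#' @param border_sigma Exponential decay length from the wall, cm.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(kind = c("place", "grid", "hd", "border", "nonspatial"),
                      baseline_rate = 0.1, peak_rate = 5,
                      place_center = c(30, 30), place_sigma = 8,
                      grid_spacing = 35, grid_orientation = 0,
                      grid_phase = c(0, 0),
                      hd_preferred = 0, hd_kappa = 4,
                      border_wall = c("W", "E", "S", "N"), border_sigma = 6) {
  kind <- match.arg(kind)
  border_wall <- match.arg(border_wall)
  stopifnot(baseline_rate >= 0, peak_rate >= baseline_rate,
            place_sigma > 0, grid_spacing > 0, hd_kappa >= 0,
            border_sigma > 0, length(place_center) == 2L,
            length(grid_phase) == 2L)
  structure(list(kind = kind, baseline_rate = baseline_rate,
                 peak_rate = peak_rate, place_center = place_center,
                 place_sigma = place_sigma, grid_spacing = grid_spacing,
                 grid_orientation = grid_orientation,
                 grid_phase = grid_phase, hd_preferred = hd_preferred,
                 hd_kappa = hd_kappa, border_wall = border_wall,
                 border_sigma = border_sigma),
            class = "cell_spec")
}

#' Burst-train specification
#'
#' Parameterises a renewal burst process: inter-burst intervals are
#' exponential, left-truncated at `min_ibi` (so the detector's minimum
#' inter-burst gap is respected by construction), intra-burst interspike
#' intervals are fixed at `intra_isi`, and the number of spikes per burst
#' is 2 plus a geometric count with the stated mean.
#'
#' @param mean_ibi Mean inter-burst interval, ms; must exceed `min_ibi`.
#' @param intra_isi Fixed intra-burst ISI, ms; must be below `min_ibi`.
#' @param spikes_per_burst_mean Mean spikes per burst (`>= 2`); a mean of
#'   exactly 2 gives two spikes in every burst.
#' @param min_ibi Minimum inter-burst interval, ms.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(mean_ibi = 500, intra_isi = 4,
                       spikes_per_burst_mean = 2, min_ibi = 50) {
  stopifnot(intra_isi > 0, intra_isi < min_ibi, mean_ibi > min_ibi,
            spikes_per_burst_mean >= 2)
  structure(list(mean_ibi = mean_ibi, intra_isi = intra_isi,
                 spikes_per_burst_mean = spikes_per_burst_mean,
                 min_ibi = min_ibi),
            class = "burst_spec")
}

#' Simulate an open-field foraging trajectory
#'
#' Smoothed random walk emulating pellet-chasing foraging: running speed
#' follows an Ornstein-Uhlenbeck process around `mean_speed`, movement
#' direction diffuses with Gaussian increments, and the path reflects off
#' the arena walls. The stored heading equals the motion direction plus a
#' small amount of independent noise (a foraging rat mostly faces its
#' direction of travel). Deterministic given `seed`.
#'
#' The default parameters (speed 25 cm/s, direction diffusion 1.4
#' rad/sqrt(s)) give >= 90 % coverage of a 60 x 60 cm arena at 3 cm bins
#' in a 20 min session, matching the session-inclusion rule applied to
#' recorded data.
#'
#' @param duration Session length, seconds.
#' @param arena An [arena_spec()].
#' @param mean_speed Mean running speed, cm/s.
#' @param rate_hz Tracking sample rate, Hz.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param heading_noise_sd SD of the heading-vs-motion-direction noise,
#'   degrees.
#' @return A [position_track()].
#' @export
simulate_trajectory <- function(duration, arena, mean_speed = 25,
                                rate_hz = 50, seed = NULL,
                                heading_noise_sd = 3) {
  stopifnot(duration > 0, inherits(arena, "arena_spec"), mean_speed > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, floor(duration * rate_hz))
  dt <- 1 / rate_hz
  tau_s <- 1                      # speed relaxation time, s
  sigma_s <- 0.45 * mean_speed    # speed fluctuation scale, cm/s
  dir_diff <- 1.4                 # direction diffusion, rad / sqrt(s)
  x <- y <- s <- phi <- numeric(n)
  x[1] <- stats::runif(1, 0.2, 0.8) * arena$width
  y[1] <- stats::runif(1, 0.2, 0.8) * arena$height
  s[1] <- mean_speed
  phi[1] <- stats::runif(1, 0, 2 * pi)
  eps_s <- stats::rnorm(n) * sigma_s * sqrt(2 * dt / tau_s)
  eps_p <- stats::rnorm(n) * dir_diff * sqrt(dt)
  for (i in 2:n) {
    s[i] <- max(0, s[i - 1] + (mean_speed - s[i - 1]) * dt / tau_s + eps_s[i])
    p <- phi[i - 1] + eps_p[i]
    nx <- x[i - 1] + s[i] * cos(p) * dt
    ny <- y[i - 1] + s[i] * sin(p) * dt
    if (nx < 0)            { nx <- -nx;                  p <- pi - p }
    if (nx > arena$width)  { nx <- 2 * arena$width - nx; p <- pi - p }
    if (ny < 0)            { ny <- -ny;                  p <- -p }
    if (ny > arena$height) { ny <- 2 * arena$height - ny; p <- -p }
    x[i] <- min(max(nx, 0), arena$width)
    y[i] <- min(max(ny, 0), arena$height)
    phi[i] <- p
  }
  heading <- (phi * 180 / pi +
                stats::rnorm(n, 0, heading_noise_sd)) %% 360
  position_track(t = (seq_len(n) - 1) * dt, x = x, y = y,
                 heading = heading, rate_hz = rate_hz, arena = arena)
}

#' Evaluate a tuning model
#'
#' Returns the instantaneous firing rate of a [cell_spec()] at the given
#' position(s) and heading(s). Vectorised over `x`, `y`, `heading`.
#'
#' @param spec A [cell_spec()].
#' @param x,y Position, cm.
#' @param heading Head direction, degrees (used by `hd` cells only).
#' @return Firing rate(s) in Hz.
#' @export
rate_at <- function(spec, x, y, heading = 0) {
  stopifnot(inherits(spec, "cell_spec"))
  b <- spec$baseline_rate
  a <- spec$peak_rate - spec$baseline_rate
  switch(spec$kind,
    nonspatial = rep_len(b, max(length(x), length(heading))),
    place = {
      d2 <- (x - spec$place_center[1])^2 + (y - spec$place_center[2])^2
      b + a * exp(-d2 / (2 * spec$place_sigma^2))
    },
    grid = {
      k <- 4 * pi / (sqrt(3) * spec$grid_spacing)
      th <- (spec$grid_orientation + c(0, 60, 120)) * pi / 180
      u <- 0
      dx <- x - spec$grid_phase[1]
      dy <- y - spec$grid_phase[2]
      for (j in 1:3)
        u <- u + cos(k * (dx * cos(th[j]) + dy * sin(th[j])))
      b + a * pmax(u / 3, 0)
    },
    hd = {
      dh <- (heading - spec$hd_preferred) * pi / 180
      b + a * exp(spec$hd_kappa * (cos(dh) - 1))
    },
    border = rate_at_border(spec, x, y))
}

# Border tuning needs to know where the far walls are; the arena extent is
# taken from the spec's `arena` attribute when present (set by
# generate_spikes), else from a 60 cm default.
rate_at_border <- function(spec, x, y) {
  arena <- attr(spec, "arena")
  w <- if (is.null(arena)) 60 else arena$width
  h <- if (is.null(arena)) 60 else arena$height
  d <- switch(spec$border_wall, W = x, E = w - x, S = y, N = h - y)
  spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) *
    exp(-pmax(d, 0) / spec$border_sigma)
}

#' Generate a spike train from a trajectory and a tuning model
#'
#' Inhomogeneous Poisson spiking by thinning: candidate spikes are drawn
#' from a homogeneous Poisson process at the maximum rate along the track
#' (with a 5 % safety margin for positions interpolated between samples)
#' and accepted with probability `rate/rate_max` at the interpolated
#' position and nearest-sample heading. Deterministic given `seed`.
#'
#' @param track A [position_track()].
#' @param spec A [cell_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [spike_train()] spanning the track's duration.
#' @export
generate_spikes <- function(track, spec, seed = NULL) {
  stopifnot(inherits(track, "position_track"), inherits(spec, "cell_spec"))
  if (!is.null(seed)) set.seed(seed)
  attr(spec, "arena") <- track$arena
  lam <- rate_at(spec, track$x, track$y, track$heading)
  dur <- track_duration(track)
  lmax <- max(lam) * 1.05
  if (lmax <= 0) return(spike_train(numeric(0), duration = dur))
  n <- stats::rpois(1, lmax * dur)
  if (n == 0) return(spike_train(numeric(0), duration = dur))
  cand <- sort(stats::runif(n, 0, dur))
  cx <- stats::approx(track$t, track$x, cand, rule = 2)$y
  cy <- stats::approx(track$t, track$y, cand, rule = 2)$y
  ih <- pmin(pmax(findInterval(cand, track$t), 1L), length(track$t))
  lc <- rate_at(spec, cx, cy, track$heading[ih])
  keep <- stats::runif(n) < pmin(lc / lmax, 1)
  spike_train(cand[keep], duration = dur)
}

#' Generate a burst-structured spike train with known ground truth
#'
#' Renewal process alternating truncated-exponential inter-burst intervals
#' with bursts of fixed-ISI spikes. Bursts that would overrun `duration`
#' are not emitted. Returns the exact number of emitted bursts, so the
#' burst detector can be checked end to end.
#'
#' @param spec A [burst_spec()].
#' @param duration Train length, seconds.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with elements `spikes` (a [spike_train()]) and
#'   `n_bursts` (integer ground truth).
#' @export
generate_burst_train <- function(spec, duration, seed = NULL) {
  stopifnot(inherits(spec, "burst_spec"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  mean_ibi <- spec$mean_ibi / 1000
  min_ibi <- spec$min_ibi / 1000
  isi <- spec$intra_isi / 1000
  p_geom <- 1 / (spec$spikes_per_burst_mean - 1)  # mean(2 + geom) = target
  t <- 0
  times <- vector("list", 64L)
  nb <- 0L
  repeat {
    gap <- min_ibi + stats::rexp(1, 1 / (mean_ibi - min_ibi))
    k <- if (p_geom >= 1) 2L else 2L + stats::rgeom(1, p_geom)
    st <- t + gap + (0:(k - 1L)) * isi
    if (st[k] > duration) break
    nb <- nb + 1L
    if (nb > length(times)) times <- c(times, vector("list", length(times)))
    times[[nb]] <- st
    t <- st[k]
  }
  list(spikes = spike_train(unlist(times[seq_len(nb)]), duration = duration),
       n_bursts = nb)
}

#' Synthetic battery of ground-truth-labelled units
#'
#' Builds the specifications for a labelled battery used in recovery and
#' specificity experiments: `n_per_type` cells each of kinds `place`,
#' `grid`, `hd` and, optionally, `border`, plus one rate-matched
#' nonspatial control per spatial cell (same mean rate along the paired
#' trajectory, no tuning) emulating a lesion condition in which firing
#' persists but tuning vanishes.
#'
#' Place-field centres are drawn from the central half of the arena: a
#' Gaussian field truncated by a wall has genuinely ambiguous place/border
#' ground truth, which a labelled battery must avoid. Grid orientation,
#' phase, preferred head direction and border wall are randomised.
#'
#' @param n_per_type Number of cells per spatial type.
#' @param arena An [arena_spec()].
#' @param seed Integer seed for the spec draw.
#' @param types Character vector of spatial kinds to include.
#' @return A list of lists with elements `kind` (ground-truth label) and
#'   `spec` (a [cell_spec()]); nonspatial controls carry `matched_to`, the
#'   index of their paired spatial cell, and a `baseline_rate` of `NA` to
#'   be filled in against the paired trajectory (see
#'   [rate_matched_control()]).
#' @export
battery_specs <- function(n_per_type = 100, arena = arena_spec(60),
                          seed = 1, types = c("place", "grid", "hd")) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ty in types) {
    for (i in seq_len(n_per_type)) {
      sp <- switch(ty,
        place = cell_spec("place",
          place_center = c(stats::runif(1, 0.25, 0.75) * arena$width,
                           stats::runif(1, 0.25, 0.75) * arena$height)),
        grid = cell_spec("grid",
          grid_orientation = stats::runif(1, 0, 60),
          grid_phase = c(stats::runif(1, 0, arena$width),
                         stats::runif(1, 0, arena$height))),
        hd = cell_spec("hd", hd_preferred = stats::runif(1, 0, 360)),
        border = cell_spec("border",
          border_wall = sample(c("N", "S", "E", "W"), 1)))
      out[[length(out) + 1L]] <- list(kind = ty, spec = sp)
    }
  }
  out
}

#' Rate-matched nonspatial control
#'
#' Returns a nonspatial [cell_spec()] whose constant rate equals the mean
#' rate of `spec` along `track`, so that a spatial cell and its control
#' emit comparable spike counts and differ only in tuning.
#'
#' @param spec A spatial [cell_spec()].
#' @param track The [position_track()] the pair will be simulated on.
#' @return A nonspatial [cell_spec()].
#' @export
rate_matched_control <- function(spec, track) {
  attr(spec, "arena") <- track$arena
  m <- mean(rate_at(spec, track$x, track$y, track$heading))
  cell_spec("nonspatial", baseline_rate = m, peak_rate = m)
}
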