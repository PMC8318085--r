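#' Arena geometry
#'
#' Describes a rectangular, walled open-field arena. Coordinates are
#' continuous centimetres with the origin at the lower-left corner, so all
#' positions lie in `[0, width] x [0, height]`.
#'
#' @param width Arena width in cm (x extent). Must be positive.
#' @param height Arena height in cm (y extent); defaults to `width`
#'   (square arena).
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec(60)        # the small square arena
#' arena_spec(105, 105)  # the large arena
#' @export
arena_spec <- function(width, height = width) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (width <= 0 || height <= 0) stop("arena width and height must be > 0")
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena %g x %g cm, origin lower-left>\n", x$width, x$height))
  invisible(x)
}

#' Timestamped position and head-direction track
#'
#' Validated container for animal tracking data: timestamps (seconds,
#' strictly increasing), x/y position (cm, within the arena bounds) and
#' head direction (degrees, stored in `[0, 360)`). Samples falling outside
#' the arena (e.g. tracking jitter at the walls) are clipped to the bounds
#' and counted in a warning.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param x,y Numeric vectors of positions in cm.
#' @param heading Numeric vector of head directions in degrees; wrapped
#'   modulo 360 on construction.
#' @param rate_hz Nominal tracking sample rate in Hz (default 50, a typical
#'   overhead-camera rate).
#' @param arena An [arena_spec()].
#' @return An object of class `position_track` with fields `t`, `x`, `y`,
#'   `heading`, `rate_hz`, `arena`.
#' @export
position_track <- function(t, x, y, heading, rate_hz = 50, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  n <- length(t)
  if (n == 0L) stop("position track must contain at least one sample")
  if (length(x) != n || length(y) != n || length(heading) != n)
    stop("t, x, y and heading must have equal length")
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("position track contains missing values")
  if (n > 1L && any(diff(t) <= 0))
    stop("sample times must be strictly increasing")
  oob <- sum(x < 0 | x > arena$width | y < 0 | y > arena$height)
  if (oob > 0L) {
    warning(sprintf("%d sample(s) outside arena bounds were clipped", oob))
    x <- pmin(pmax(x, 0), arena$width)
    y <- pmin(pmax(y, 0), arena$height)
  }
  heading <- as.numeric(heading) %% 360
  structure(list(t = t, x = x, y = y, heading = heading,
                 rate_hz = as.numeric(rate_hz), arena = arena),
            class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf(
    "<position_track: %d samples, %.1f s at %g Hz, arena %g x %g cm>\n",
    length(x$t), track_duration(x), x$rate_hz, x$arena$width, x$arena$height))
  invisible(x)
}

# Tracked duration in seconds (span of samples plus one sample interval).
track_duration <- function(track) {
  diff(range(track$t)) + 1 / track$rate_hz
}

#' Sorted spike train of one unit
#'
#' Spike times of a single sorted unit, in seconds from recording start.
#' Times are sorted ascending on construction; exact duplicate times (at
#' stored precision) are dropped with a warning, since a real unit cannot
#' fire twice at the same instant.
#'
#' @param times Numeric vector of spike times in seconds, all in
#'   `[0, duration]`.
#' @param duration Recording duration in seconds. If `NULL`, taken as the
#'   last spike time (with a message).
#' @param waveform Optional [waveform_summary()] (mean spike waveform).
#' @return An object of class `spike_train` with fields `times`,
#'   `duration`, `waveform`.
#' @export
spike_train <- function(times, duration = NULL, waveform = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times contain missing values")
  if (any(times < 0)) stop("spike times must be non-negative")
  times <- sort(times)
  if (anyDuplicated(times)) {
    warning("duplicate spike times dropped")
    times <- unique(times)
  }
  if (is.null(duration)) {
    duration <- if (length(times)) max(times) else 0
    message("spike train duration taken from last spike time")
  }
  duration <- as.numeric(duration)
  if (length(times) && max(times) > duration)
    stop("spike times exceed the stated duration")
  if (!is.null(waveform)) stopifnot(inherits(waveform, "waveform_summary"))
  structure(list(times = times, duration = duration, waveform = waveform),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %.1f s (%.3f Hz)%s>\n",
              length(x$times), x$duration,
              if (x$duration > 0) length(x$times) / x$duration else NA_real_,
              if (is.null(x$waveform)) "" else ", with waveform"))
  invisible(x)
}

#' Mean spike waveform
#'
#' @param samples Numeric vector of waveform values in microvolts, one per
#'   sample. Must be non-empty and finite.
#' @param sample_interval Time between samples in microseconds (e.g.
#'   20.8 us for a 48 kHz acquisition system).
#' @return An object of class `waveform_summary`.
#' @export
waveform_summary <- function(samples, sample_interval) {
  samples <- as.numeric(samples)
  if (!length(samples) || !all(is.finite(samples)))
    stop("waveform samples must be non-empty and finite")
  stopifnot(is.numeric(sample_interval), sample_interval > 0)
  structure(list(samples = samples,
                 sample_interval = as.numeric(sample_interval)),
            class = "waveform_summary")
}

#' 2x2 presence/absence contingency table
#'
#' Counts of recordings with and without a given cell type in a control and
#' a lesion condition: `control_with` of `control_total` control recordings
#' contained the cell type, and likewise for the lesion group.
#'
#' @param control_with,control_total Counts for the control condition.
#' @param lesion_with,lesion_total Counts for the lesion condition.
#' @return An object of class `contingency_table`.
#' @examples
#' # spatial-cell presence in control vs anterior-thalamic-lesion recordings
#' contingency_table(15, 53, 0, 47)
#' @export
contingency_table <- function(control_with, control_total,
                              lesion_with, lesion_total) {
  v <- c(control_with, control_total, lesion_with, lesion_total)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop("contingency counts must be non-negative integers")
  if (control_with > control_total)
    stop("control_with exceeds control_total")
  if (lesion_with > lesion_total)
    stop("lesion_with exceeds lesion_total")
  structure(list(control_with = as.integer(control_with),
                 control_total = as.integer(control_total),
                 lesion_with = as.integer(lesion_with),
                 lesion_total = as.integer(lesion_total)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency: control %d/%d, lesion %d/%d>\n",
              x$control_with, x$control_total,
              x$lesion_with, x$lesion_total))
  invisible(x)
}

#' Continuous object-recognition session
#'
#' Per-trial exploration times from a continuous recognition task in which
#' every trial presents one new (novel) object next to the previous trial's
#' object (now familiar). The first trial of a session may have no familiar
#' object; its familiar time is then `NA`.
#'
#' @param novel Numeric vector of per-trial novel-object exploration times
#'   in seconds.
#' @param familiar Numeric vector of familiar-object exploration times;
#'   `NA` allowed for trials without a familiar object (e.g. trial 1).
#' @return An object of class `recognition_session`.
#' @export
recognition_session <- function(novel, familiar) {
  novel <- as.numeric(novel); familiar <- as.numeric(familiar)
  if (!length(novel)) stop("at least one trial required")
  if (length(familiar) != length(novel))
    stop("novel and familiar must have equal length")
  if (anyNA(novel) || any(novel < 0) || any(familiar < 0, na.rm = TRUE))
    stop("exploration times must be non-negative")
  structure(list(novel = novel, familiar = familiar),
            class = "recognition_session")
}

#' T-maze spatial-alternation session
#'
#' @param choices Logical vector: `TRUE` where the animal chose the arm
#'   opposite its forced sample run (a correct alternation).
#' @return An object of class `alternation_session`.
#' @export
alternation_session <- function(choices) {
  choices <- as.logical(choices)
  if (!length(choices) || anyNA(choices))
    stop("choices must be a non-empty logical vector without NA")
  structure(list(choices = choices), class = "alternation_session")
}
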