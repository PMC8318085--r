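#' Read and write tracking files
#'
#' The native track format is tab-separated text with columns
#' `t`, `x`, `y`, `heading` (seconds, cm, cm, degrees) and `#`-prefixed
#' header lines carrying metadata (`#arena=WxH`, `#rate_hz=R`). Axona or
#' other vendor binary formats are out of scope; export to this dialect
#' first.
#'
#' @param path Path to the track file.
#' @param arena An [arena_spec()]. If `NULL`, the `#arena=` header line is
#'   used; an error is raised if neither is available.
#' @return `read_track()` returns a validated [position_track()];
#'   `write_track()` returns `path` invisibly.
#' @export
read_track <- function(path, arena = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  meta <- read_header_meta(path)
  if (is.null(arena)) {
    if (is.null(meta$arena))
      stop("no arena given and no #arena= header in ", path)
    wh <- as.numeric(strsplit(meta$arena, "x", fixed = TRUE)[[1]])
    arena <- arena_spec(wh[1], wh[2])
  }
  rate_hz <- if (is.null(meta$rate_hz)) 50 else as.numeric(meta$rate_hz)
  d <- read_delim_checked(path, c("t", "x", "y", "heading"))
  position_track(d$t, d$x, d$y, d$heading, rate_hz = rate_hz, arena = arena)
}

#' @rdname read_track
#' @param track A [position_track()] to write.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "position_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#arena=%gx%g", track$arena$width, track$arena$height),
    sprintf("#rate_hz=%g", track$rate_hz),
    "t\tx\ty\theading"), con)
  utils::write.table(
    data.frame(t = track$t, x = track$x, y = track$y,
               heading = track$heading),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write spike-time files
#'
#' Spike files are tab-separated text with a single column `t` of spike
#' times in seconds and a `#duration=` header line giving the recording
#' length in seconds. Times are sorted on read; if the duration header is
#' absent the last spike time is used (with a message).
#'
#' @param path Path to the spike file.
#' @return `read_spikes()` returns a [spike_train()]; `write_spikes()`
#'   returns `path` invisibly.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  meta <- read_header_meta(path)
  d <- read_delim_checked(path, "t", allow_empty = TRUE)
  dur <- if (is.null(meta$duration)) NULL else as.numeric(meta$duration)
  spike_train(d$t, duration = dur)
}

#' @rdname read_spikes
#' @param spikes A [spike_train()] to write.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#duration=%.10g", spikes$duration), "t"), con)
  if (length(spikes$times))
    writeLines(sprintf("%.10g", spikes$times), con)
  invisible(path)
}

#' Read and write presence contingency tables
#'
#' The file mirrors the layout of a condition-level presence table: a
#' header `label control lesion` and two rows, `with` (recordings where at
#' least one cell of the type was present) and `total` (all recordings),
#' tab-separated.
#'
#' @param path Path to the contingency file.
#' @return `read_contingency()` returns a [contingency_table()];
#'   `write_contingency()` returns `path` invisibly.
#' @export
read_contingency <- function(path) {
  if (!file.exists(path)) stop("contingency file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("label", "control", "lesion")
  if (!all(need %in% names(d)))
    stop("contingency file must have columns: ", paste(need, collapse = ", "))
  row <- function(lab) {
    i <- match(lab, d$label)
    if (is.na(i)) stop("contingency file missing row '", lab, "'")
    d[i, c("control", "lesion")]
  }
  w <- row("with"); tot <- row("total")
  contingency_table(w$control, tot$control, w$lesion, tot$lesion)
}

#' @rdname read_contingency
#' @param table A [contingency_table()] to write.
#' @export
write_contingency <- function(table, path) {
  stopifnot(inherits(table, "contingency_table"))
  d <- data.frame(label = c("with", "total"),
                  control = c(table$control_with, table$control_total),
                  lesion = c(table$lesion_with, table$lesion_total))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse "#key=value" header lines into a named list.
read_header_meta <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    kv <- sub("^#", "", line)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      out[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  out
}

# Read a delimited body with the given columns, raising a parse error that
# names the first malformed line.
read_delim_checked <- function(path, cols, allow_empty = FALSE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no header row in ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
  if (!all(cols %in% header))
    stop("file ", path, " must have columns: ", paste(cols, collapse = ", "))
  rows <- body[-1L]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) {
    if (allow_empty) {
      out <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                               length(header)), header))
      return(out[cols])
    }
    stop("no data rows in ", path)
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop(sprintf("malformed row at line %d of %s",
                 bad + (length(lines) - length(body)) + 1L, path))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(header), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1L]
    stop(sprintf("non-numeric value at line %d of %s",
                 bad + (length(lines) - length(body)) + 1L, path))
  }
  colnames(m) <- header
  as.data.frame(m)[cols]
}
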