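# Independent brute-force oracles. These deliberately re-derive results
# with the most literal algorithm available (explicit loops, no shared
# code with the package internals) so that implementation and oracle can
# only agree by computing the same quantity.

# 4-connected components by stack-based flood fill.
flood_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  comps <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j))
    pix <- integer(0)
    seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pix <- c(pix, as.integer((p[2] - 1) * nx + p[1]))
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nx && q[2] >= 1 && q[2] <= ny &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(pix)
  }
  comps
}

# Canonical form of a component list for set comparison.
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

# Direct-summation Skaggs information (bits/spike) with explicit loops.
skaggs_direct <- function(occ, rate, visited) {
  tot <- 0
  for (k in which(visited)) tot <- tot + occ[k]
  lbar <- 0
  for (k in which(visited)) lbar <- lbar + occ[k] / tot * rate[k]
  if (lbar <= 0) return(NA_real_)
  info <- 0
  for (k in which(visited)) {
    if (rate[k] > 0)
      info <- info + occ[k] / tot * (rate[k] / lbar) * log2(rate[k] / lbar)
  }
  info
}

sparsity_direct <- function(occ, rate, visited) {
  tot <- sum(occ[visited])
  m1 <- 0; m2 <- 0
  for (k in which(visited)) {
    p <- occ[k] / tot
    m1 <- m1 + p * rate[k]
    m2 <- m2 + p * rate[k]^2
  }
  if (m2 <= 0) return(NA_real_)
  m1^2 / m2
}

# Per-lag Pearson autocorrelation with scalar accumulation, O(lags * bins).
brute_autocorr <- function(r, min_overlap = 20) {
  nx <- nrow(r); ny <- ncol(r)
  lx <- -(nx - 1):(nx - 1)
  ly <- -(ny - 1):(ny - 1)
  out <- matrix(NA_real_, length(lx), length(ly))
  for (a in seq_along(lx)) for (b in seq_along(ly)) {
    dx <- lx[a]; dy <- ly[b]
    n <- 0; s1 <- 0; s2 <- 0; s11 <- 0; s22 <- 0; s12 <- 0
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      i2 <- i - dx; j2 <- j - dy
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny) next
      v1 <- r[i, j]; v2 <- r[i2, j2]
      if (is.na(v1) || is.na(v2)) next
      n <- n + 1; s1 <- s1 + v1; s2 <- s2 + v2
      s11 <- s11 + v1 * v1; s22 <- s22 + v2 * v2; s12 <- s12 + v1 * v2
    }
    if (n < min_overlap) next
    den <- sqrt(n * s11 - s1^2) * sqrt(n * s22 - s2^2)
    if (den <= 0) next
    out[a, b] <- (n * s12 - s1 * s2) / den
  }
  out
}

# Literal burst scanner: walk the train, extend runs spike by spike, then
# merge events separated by less than min_ibi.
brute_bursts <- function(tms, max_isi = 6, min_spikes = 2, min_ibi = 50) {
  n <- length(tms)
  spans <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && (tms[j + 1L] - tms[j]) <= max_isi + 1e-9) j <- j + 1L
    if (j > i && (j - i + 1L) >= min_spikes)
      spans[[length(spans) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  if (length(spans) > 1L) {
    merged <- list(spans[[1L]])
    for (k in 2:length(spans)) {
      prev <- merged[[length(merged)]]
      cur <- spans[[k]]
      if (tms[cur[1L]] - tms[prev[2L]] < min_ibi - 1e-9)
        merged[[length(merged)]] <- c(prev[1L], cur[2L])
      else merged[[length(merged) + 1L]] <- cur
    }
    spans <- merged
  }
  nb <- length(spans)
  nspk <- if (nb) sum(vapply(spans, function(s) s[2L] - s[1L] + 1L,
                             integer(1))) else 0L
  list(n_bursts = nb, n_burst_spikes = nspk, spans = spans)
}

# Random spike trains mixing sparse and clustered firing, for burst
# detector stress tests.
random_burst_train <- function(n_max = 80) {
  n <- sample(2:n_max, 1)
  isis <- sample(c(2, 3, 4, 5, 5.9, 6.1, 8, 20, 49, 51, 80, 200, 500),
                 n - 1, replace = TRUE) / 1000
  t <- cumsum(c(stats::runif(1, 0, 0.05), isis))
  spike_train(t, duration = max(t) + 0.1)
}

# Random small rate map with patchy visits, for metric/autocorr oracles.
random_map <- function(nx = 10, ny = 10, p_visit = 0.9, bin_size = 3) {
  occ <- matrix(stats::rexp(nx * ny, 1) + 0.2, nx, ny)
  occ[stats::runif(nx * ny) > p_visit] <- 0
  cnt <- matrix(stats::rpois(nx * ny, 3), nx, ny)
  cnt[occ == 0] <- 0
  spatunits:::new_rate_map(occ, cnt, bin_size,
                           arena_spec(nx * bin_size, ny * bin_size))
}

# Map built directly from a rate matrix with uniform unit occupancy.
map_from_rate <- function(rate, bin_size = 3, occ = NULL) {
  nx <- nrow(rate); ny <- ncol(rate)
  if (is.null(occ)) occ <- matrix(1, nx, ny)
  spatunits:::new_rate_map(occ, rate * occ, bin_size,
                           arena_spec(nx * bin_size, ny * bin_size))
}
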