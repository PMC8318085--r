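test_that("raw rate maps satisfy the spike-count conservation identity", {
  ar <- arena_spec(60)
  for (s in 1:5) {
    tr <- simulate_trajectory(300, ar, seed = 500 + s)
    sp <- generate_spikes(tr, cell_spec("place"), seed = 600 + s)
    m <- compute_ratemap(tr, sp)
    v <- m$visited
    expect_equal(sum(m$rate[v] * m$occupancy[v]), sum(m$spike_count[v]),
                 tolerance = 1e-9)
    expect_equal(sum(m$spike_count), length(sp$times))
    expect_equal(sum(m$occupancy), spatunits:::track_duration(tr),
                 tolerance = 1 / tr$rate_hz)
  }
})

test_that("a spikeless unit yields an all-zero rate map", {
  tr <- simulate_trajectory(120, arena_spec(60), seed = 1)
  m <- compute_ratemap(tr, spike_train(numeric(0), duration = 120))
  expect_true(all(m$rate[m$visited] == 0))
  expect_true(all(is.na(m$rate[!m$visited])))
})

test_that("uniform occupancy with constant-rate firing gives per-bin rates within Poisson bounds", {
  # raster-scan track: constant speed sweep through every 3 cm bin
  ar <- arena_spec(60)
  step <- 0.5
  xs <- seq(0.25, 59.75, by = step)
  ys <- seq(0.25, 59.75, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  n <- length(gx)
  tr <- position_track(t = (seq_len(n) - 1) * 0.02, x = gx, y = gy,
                       heading = rep(0, n), rate_hz = 50, arena = ar)
  sp <- generate_spikes(tr, cell_spec("nonspatial", baseline_rate = 2,
                                      peak_rate = 2), seed = 8)
  m <- compute_ratemap(tr, sp, smoothing_sigma = 0)
  v <- m$visited
  z <- (m$rate[v] - 2) / sqrt(2 / m$occupancy[v])
  expect_gte(mean(abs(z) < 3), 0.98)
  expect_lt(abs(mean(m$rate[v]) - 2) / 2, 0.1)
})

test_that("field detection honours the nine-pixel side-sharing definition", {
  r <- matrix(0, 12, 12)
  r[3:5, 3:5] <- 1                       # 3x3 block: exactly nine pixels
  fs <- detect_firing_fields(map_from_rate(r))
  expect_length(fs$fields, 1)
  expect_equal(fs$sizes, 9L)

  r2 <- matrix(0, 12, 12)
  r2[3:4, 3:6] <- 1                      # 2x4 block: eight pixels
  expect_length(detect_firing_fields(map_from_rate(r2))$fields, 0)

  r3 <- matrix(0, 12, 12)
  r3[2:4, 2:4] <- 1
  r3[5:7, 5:7] <- 1                      # touches only diagonally
  fs3 <- detect_firing_fields(map_from_rate(r3))
  expect_length(fs3$fields, 2)
})

test_that("connected components agree with a flood-fill oracle on random maps", {
  set.seed(33)
  for (i in 1:200) {
    mask <- matrix(runif(100) < 0.45, 10, 10)
    got <- canon_components(spatunits:::label_components(mask))
    want <- canon_components(flood_components(mask))
    expect_identical(got, want)
  }
})

test_that("place-field detection thresholds at 20% of the peak rate", {
  # Gaussian bump: one field containing the peak pixel
  xc <- (1:20 - 0.5) * 3
  r <- outer(xc, xc, function(x, y) 5 * exp(-((x - 30)^2 + (y - 30)^2) / 128))
  m <- map_from_rate(r)
  pf <- detect_place_fields(m)
  expect_length(pf$fields, 1)
  expect_true(which.max(r) %in% pf$fields[[1]])

  # constant positive map: the whole visited arena is one field
  cf <- detect_place_fields(map_from_rate(matrix(2, 15, 15)))
  expect_length(cf$fields, 1)
  expect_equal(cf$sizes, 225L)

  # eight suprathreshold pixels do not make a place field
  r8 <- matrix(0.01, 12, 12)
  r8[3:4, 3:6] <- 1
  expect_length(detect_place_fields(map_from_rate(r8))$fields, 0)

  # all-zero map: empty field set
  z <- detect_place_fields(map_from_rate(matrix(0, 10, 10)))
  expect_length(z$fields, 0)
})

test_that("coverage is the fraction of visited pixels with visit counts attached", {
  ar <- arena_spec(30)
  xs <- (1:10 - 0.5) * 3
  gx <- rep(xs, times = 10); gy <- rep(xs, each = 10)
  tr <- position_track(t = seq_along(gx) * 0.02, x = gx, y = gy,
                       heading = rep(0, length(gx)), arena = ar)
  cv <- coverage(tr, 3)
  expect_equal(as.numeric(cv), 1.0)
  expect_true(all(attr(cv, "visits") >= 1))

  still <- position_track(t = c(0, 0.02, 0.04), x = rep(5, 3),
                          y = rep(5, 3), heading = rep(0, 3), arena = ar)
  expect_equal(as.numeric(coverage(still, 3)), 1 / 100)
  expect_equal(sum(attr(coverage(still, 3), "visits")), 1)
})

test_that("smoothing approximately conserves total rate mass on uniform occupancy", {
  set.seed(9)
  r <- matrix(rexp(400, 1), 20, 20)
  occ <- matrix(1, 20, 20)
  m <- spatunits:::new_rate_map(occ, r, 3, arena_spec(60),
                                smoothing_sigma = 1)
  raw_mass <- sum(m$rate * occ)
  smooth_mass <- sum(m$rate_smooth * occ)
  expect_lt(abs(smooth_mass - raw_mass) / raw_mass, 0.05)
})
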