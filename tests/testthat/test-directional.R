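# A deterministic track whose heading sweeps uniformly through [0, 360).
sweep_track <- function(n = 7200, rate_hz = 50) {
  position_track(t = (seq_len(n) - 1) / rate_hz,
                 x = rep(30, n) + sin(seq_len(n) / 500),
                 y = rep(30, n) + cos(seq_len(n) / 500),
                 heading = (seq_len(n) * 360 / 720) %% 360,
                 rate_hz = rate_hz, arena = arena_spec(60))
}

test_that("head-direction tuning separates uniform from concentrated firing", {
  tr <- sweep_track()
  # spikes at a constant rate regardless of heading: flat tuning
  flat <- hd_tuning(tr, spike_train(seq(0.1, 143, by = 0.1),
                                    duration = 144))
  expect_lt(flat$resultant_length, 0.05)

  # spikes emitted only while heading sits in one 5-degree bin
  in_bin <- tr$t[tr$heading >= 90 & tr$heading < 95]
  conc <- hd_tuning(tr, spike_train(in_bin + 1e-4, duration = 144))
  expect_gt(conc$resultant_length, 0.95)
  expect_lt(abs(conc$preferred_direction - 92.5), 5)
  expect_equal(length(conc$bin_centers), 72)
})

test_that("zero-dwell heading bins are masked and excluded", {
  n <- 1000
  tr <- position_track(t = (seq_len(n) - 1) / 50, x = rep(30, n),
                       y = rep(30, n),
                       heading = runif(n, 0, 180),  # never faces south
                       arena = arena_spec(60))
  h <- hd_tuning(tr, spike_train(seq(0.1, 19, by = 0.5), duration = 20))
  expect_true(all(is.na(h$bin_rate[h$dwell == 0])))
  expect_true(all(h$dwell[h$bin_centers > 180] == 0))
})

test_that("preferred direction is recovered from synthetic HD cells", {
  ar <- arena_spec(60)
  for (s in 1:10) {
    tr <- simulate_trajectory(600, ar, seed = 1100 + s)
    pref <- (s * 36) %% 360
    sp <- generate_spikes(tr, cell_spec("hd", hd_preferred = pref),
                          seed = 1200 + s)
    h <- hd_tuning(tr, sp)
    err <- abs(((h$preferred_direction - pref + 180) %% 360) - 180)
    expect_lt(err, 10)
    expect_true(h$resultant_length >= 0 && h$resultant_length <= 1)
  }
})

test_that("the autocorrelogram matches a brute-force oracle and its invariants", {
  set.seed(55)
  for (i in 1:20) {
    m <- random_map(8, 8)
    ac <- spatial_autocorrelation(m, min_overlap = 5)
    r <- m$rate_smooth
    r[!m$visited] <- NA
    want <- brute_autocorr(r, min_overlap = 5)
    expect_equal(ac$values, want, tolerance = 1e-10)
    # central value 1, point symmetry
    expect_equal(ac$values[m$nx, m$ny], 1, tolerance = 1e-12)
    expect_equal(ac$values, ac$values[rev(seq_len(nrow(ac$values))),
                                      rev(seq_len(ncol(ac$values)))],
                 tolerance = 1e-12)
  }
})

test_that("grid statistics recover a noiseless synthetic grid", {
  xc <- (1:20 - 0.5) * 3
  spec <- cell_spec("grid", grid_spacing = 35, grid_orientation = 10,
                    grid_phase = c(5, 9))
  attr(spec, "arena") <- arena_spec(60)
  r <- outer(xc, xc, function(x, y) rate_at(spec, x, y))
  g <- grid_score(spatial_autocorrelation(map_from_rate(r)))
  expect_gt(g$grid_score, 0.5)
  expect_lt(abs(g$spacing - 35) / 35, 0.15)
  expect_equal(g$n_peaks, 6L)
  expect_true(g$orientation >= 0 && g$orientation < 60)
})

test_that("grid score is invariant to rate rescaling and map translation", {
  xc <- (1:20 - 0.5) * 3
  scores <- vapply(0:3, function(j) {
    spec <- cell_spec("grid", grid_spacing = 35, grid_orientation = 10,
                      grid_phase = c(5 + 7 * j, 9 + 5 * j))
    attr(spec, "arena") <- arena_spec(60)
    r <- outer(xc, xc, function(x, y) rate_at(spec, x, y))
    grid_score(spatial_autocorrelation(map_from_rate(r)))$grid_score
  }, numeric(1))
  expect_lt(max(scores) - min(scores), 0.05)

  spec <- cell_spec("grid", grid_spacing = 35, grid_orientation = 10,
                    grid_phase = c(5, 9))
  attr(spec, "arena") <- arena_spec(60)
  r <- outer(xc, xc, function(x, y) rate_at(spec, x, y))
  s1 <- grid_score(spatial_autocorrelation(map_from_rate(r)))$grid_score
  s2 <- grid_score(spatial_autocorrelation(map_from_rate(r * 6)))$grid_score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("centrally symmetric maps are negative controls for the grid score", {
  # the square-window autocorrelogram of a 4-fold-symmetric map has
  # r90 ~ 1, which drives the score negative; see the methods vignette
  xc <- (1:20 - 0.5) * 3
  disk <- outer(xc, xc, function(x, y)
    as.numeric(sqrt((x - 30)^2 + (y - 30)^2) < 20))
  g <- grid_score(spatial_autocorrelation(map_from_rate(disk)))
  expect_gt(g$rotations["r90"], 0.9)
  expect_lte(g$grid_score, 0)

  # noisy synthetic place cells stay well below the grid threshold
  ar <- arena_spec(60)
  scores <- vapply(1:6, function(s) {
    tr <- simulate_trajectory(1200, ar, seed = 1300 + s)
    sp <- generate_spikes(tr, cell_spec("place",
                                        place_center = c(24 + s, 30)),
                          seed = 1400 + s)
    grid_score(spatial_autocorrelation(compute_ratemap(tr, sp)))$grid_score
  }, numeric(1))
  expect_lt(max(scores), classification_thresholds()$grid)
  expect_lte(mean(scores), 0)
})

test_that("border score is high for wall strips and negative for central fields", {
  # one-bin-wide strip along the west wall
  r <- matrix(0, 20, 20)
  r[1, ] <- 3
  m <- map_from_rate(r)
  fs <- detect_firing_fields(m)
  b <- border_score(m, fs)
  expect_equal(b$wall_coverage, 1)
  expect_lt(b$mean_field_distance_to_wall, 0.1)
  expect_gt(b$border_score, 0.8)

  # compact field at the arena centre
  r2 <- matrix(0, 20, 20)
  r2[10:12, 10:12] <- 3
  m2 <- map_from_rate(r2)
  b2 <- border_score(m2, detect_firing_fields(m2))
  expect_lt(b2$border_score, 0)

  # no fields: undefined
  empty <- border_score(m, detect_firing_fields(map_from_rate(matrix(0, 20, 20))))
  expect_true(is.na(empty$border_score))
})

test_that("synthetic border cells out-score rate-matched place cells", {
  ar <- arena_spec(60)
  for (s in 1:6) {
    tr <- simulate_trajectory(1200, ar, seed = 1500 + s)
    mb <- compute_ratemap(tr, generate_spikes(
      tr, cell_spec("border", border_wall = c("N", "S", "E", "W")[1 + s %% 4]),
      seed = 1600 + s))
    mp <- compute_ratemap(tr, generate_spikes(
      tr, cell_spec("place", place_center = c(25 + s, 30)),
      seed = 1700 + s))
    sb <- border_score(mb, detect_place_fields(mb))$border_score
    sp <- border_score(mp, detect_place_fields(mp))$border_score
    expect_gt(sb, sp)
  }
})
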