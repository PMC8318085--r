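test_that("trajectory and spike generators are bit-reproducible under a fixed seed", {
  ar <- arena_spec(60)
  t1 <- simulate_trajectory(120, ar, seed = 42)
  t2 <- simulate_trajectory(120, ar, seed = 42)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$heading, t2$heading)
  sp1 <- generate_spikes(t1, cell_spec("place"), seed = 7)
  sp2 <- generate_spikes(t2, cell_spec("place"), seed = 7)
  expect_identical(sp1$times, sp2$times)
  b1 <- generate_burst_train(burst_spec(), 60, seed = 9)
  b2 <- generate_burst_train(burst_spec(), 60, seed = 9)
  expect_identical(b1$spikes$times, b2$spikes$times)
  expect_identical(b1$n_bursts, b2$n_bursts)
})

test_that("default 20-min trajectories cover at least 90% of the arena", {
  ar <- arena_spec(60)
  for (s in 1:20) {
    tr <- simulate_trajectory(1200, ar, seed = s)
    expect_gte(as.numeric(coverage(tr, 3)), 0.90)
  }
})

test_that("realised speed tracks the requested mean speed", {
  ar <- arena_spec(60)
  for (s in 1:10) {
    tr <- simulate_trajectory(300, ar, mean_speed = 25, seed = 100 + s)
    v <- mean(sqrt(diff(tr$x)^2 + diff(tr$y)^2)) * tr$rate_hz
    expect_lt(abs(v - 25) / 25, 0.20)
  }
})

test_that("tuning models take their stated extreme values", {
  pl <- cell_spec("place", place_center = c(20, 40), peak_rate = 5,
                  baseline_rate = 0.1)
  expect_equal(rate_at(pl, 20, 40), 5)
  far <- rate_at(pl, 55, 5)
  expect_lt(far, 0.11)

  hd <- cell_spec("hd", hd_preferred = 30, hd_kappa = 8, peak_rate = 5,
                  baseline_rate = 0.1)
  expect_equal(rate_at(hd, 10, 10, heading = 30), 5)
  expect_lt(rate_at(hd, 10, 10, heading = 210), 0.11)

  ns <- cell_spec("nonspatial", baseline_rate = 2, peak_rate = 2)
  expect_equal(rate_at(ns, c(1, 30), c(1, 30)), c(2, 2))
})

test_that("grid tuning is periodic under a lattice translation", {
  spec <- cell_spec("grid", grid_spacing = 35, grid_orientation = 17,
                    grid_phase = c(4, 9))
  th <- (17 + 30) * pi / 180
  lat <- 35 * c(cos(th), sin(th))
  set.seed(5)
  x <- runif(50, 0, 200); y <- runif(50, 0, 200)
  expect_equal(rate_at(spec, x + lat[1], y + lat[2]),
               rate_at(spec, x, y), tolerance = 1e-9)
})

test_that("thinning reproduces the Poisson expectation for a constant-rate unit", {
  ar <- arena_spec(60)
  tr <- simulate_trajectory(1200, ar, seed = 77)
  spec <- cell_spec("nonspatial", baseline_rate = 5, peak_rate = 5)
  counts <- vapply(1:20, function(s)
    length(generate_spikes(tr, spec, seed = s)$times), numeric(1))
  expected <- 5 * 1200
  sd1 <- sqrt(expected)
  expect_true(all(abs(counts - expected) < 4 * sd1))
  expect_lt(abs(mean(counts) - expected), 3 * sd1 / sqrt(20))
})

test_that("a zero-rate specification yields an empty train", {
  tr <- simulate_trajectory(60, arena_spec(60), seed = 3)
  spec <- cell_spec("nonspatial", baseline_rate = 0, peak_rate = 0)
  sp <- generate_spikes(tr, spec, seed = 4)
  expect_length(sp$times, 0)
  expect_equal(sp$duration, spatunits:::track_duration(tr))
})

test_that("place fields are recovered at the specified centre", {
  ar <- arena_spec(60)
  for (s in 1:10) {
    tr <- simulate_trajectory(1200, ar, seed = 200 + s)
    ctr <- c(15 + 3 * s, 45 - 2 * s)
    sp <- generate_spikes(tr, cell_spec("place", place_center = ctr),
                          seed = 300 + s)
    m <- compute_ratemap(tr, sp)
    pk <- which(m$rate_smooth == max(m$rate_smooth, na.rm = TRUE),
                arr.ind = TRUE)[1, ]
    ctr_bin <- floor(ctr / 3) + 1
    expect_lte(max(abs(pk - ctr_bin)), 2)
  }
})

test_that("burst-train generation matches its renewal expectation", {
  spec <- burst_spec(mean_ibi = 500, intra_isi = 4,
                     spikes_per_burst_mean = 2, min_ibi = 50)
  nb <- vapply(1:10, function(s)
    generate_burst_train(spec, 60, seed = s)$n_bursts, integer(1))
  # cycle length ~ mean_ibi + one intra-burst ISI => ~ 60/0.504 bursts
  expect_true(all(abs(nb - 60 / 0.5) < 30))
  # with mean 2 spikes per burst every intra-burst ISI equals intra_isi
  gt <- generate_burst_train(spec, 60, seed = 11)
  isi <- diff(gt$spikes$times)
  expect_equal(unique(round(isi[isi < 0.006 + 1e-9], 9)), 0.004)
})

test_that("the burst detector recovers generator ground truth exactly", {
  spec <- burst_spec(mean_ibi = 500, intra_isi = 4,
                     spikes_per_burst_mean = 3, min_ibi = 50)
  for (s in 1:10) {
    gt <- generate_burst_train(spec, 60, seed = 400 + s)
    det <- detect_bursts(gt$spikes)
    expect_identical(det$n_bursts, gt$n_bursts)
  }
})

test_that("rate-matched controls reproduce the paired cell's mean rate", {
  tr <- simulate_trajectory(600, arena_spec(60), seed = 21)
  spec <- cell_spec("place", place_center = c(30, 30))
  ctrl <- rate_matched_control(spec, tr)
  expect_equal(ctrl$kind, "nonspatial")
  attr(spec, "arena") <- tr$arena
  expect_equal(ctrl$baseline_rate,
               mean(rate_at(spec, tr$x, tr$y, tr$heading)))
})
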