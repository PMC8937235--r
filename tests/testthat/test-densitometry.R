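test_that("extension efficiency matches partial-sum hand calculation", {
  expect_equal(extension_efficiency(lane_profile(c(0, 10))), 1)
  expect_equal(extension_efficiency(lane_profile(c(10, 0))), 0)
  expect_equal(extension_efficiency(lane_profile(c(1, 1, 1, 1))),
               c(3 / 4, 2 / 3, 1 / 2))
  # zero denominator (no signal at or beyond b-1) is missing, never 0 or 1
  E <- extension_efficiency(lane_profile(c(5, 0, 0)))
  expect_equal(E[1], 0)
  expect_true(is.na(E[2]))
})

test_that("survival fractions telescope the efficiency product exactly", {
  lane <- lane_profile(c(1, 1, 1, 1))
  expect_equal(survival_fraction(lane, 2), 0.5)
  expect_equal(survival_fraction(lane, 1), 0.75)
  set.seed(12)
  for (i in 1:20) {
    I <- sample(0:50, 8, replace = TRUE)
    I[1] <- I[1] + 1  # keep the lane non-empty
    lane <- lane_profile(I)
    E <- extension_efficiency(lane)
    sf <- vapply(1:7, survival_fraction, numeric(1), lane = lane)
    for (k in 1:7) {
      if (!anyNA(E[1:k])) expect_equal(prod(E[1:k]), sf[k], tolerance = 1e-12)
    }
    expect_true(all(diff(sf) <= 1e-12))  # survival is non-increasing
  }
  expect_error(survival_fraction(lane_profile(c(0, 0)), 1), "empty lane")
})

test_that("lane statistics are invariant to intensity rescaling", {
  lane <- simulate_lane(n_junctions = 12, e0 = 0.85, A = 0.4,
                        pitch_bp = 11.3, n_molecules = 1)
  lane_c <- lane_profile(lane$intensity * 3172.5)
  expect_equal(extension_efficiency(lane_c), extension_efficiency(lane))
  expect_equal(survival_fraction(lane_c, 5), survival_fraction(lane, 5))
  p1 <- periodicity(extension_efficiency(lane))
  p2 <- periodicity(extension_efficiency(lane_c))
  expect_identical(p1$period_bp, p2$period_bp)
})

test_that("mean efficiency averages the requested junctions", {
  expect_equal(mean_efficiency(rep(0.8, 6)), 0.8)
  expect_equal(mean_efficiency(c(3 / 4, 2 / 3, 1 / 2), through = 3),
               (3 / 4 + 2 / 3 + 1 / 2) / 3)
  expect_equal(mean_efficiency(c(0.9, 0.4), type = "geometric"),
               sqrt(0.36))
  expect_error(mean_efficiency(c(0.8, NA, 0.7)), "undefined")
  lane <- simulate_lane(n_junctions = 9, e0 = 0.9, A = 0)
  expect_equal(mean_efficiency(extension_efficiency(lane)), 0.9)
})

test_that("the periodicity estimator recovers injected periods within 0.5 bp", {
  for (pitch in seq(8, 15, by = 1)) {
    lane <- simulate_lane(n_junctions = 9, e0 = 0.8, A = 0.5,
                          pitch_bp = pitch, phase_offset_bp = 1)
    p <- periodicity(extension_efficiency(lane))
    expect_lt(abs(p$period_bp - pitch), 0.5)
  }
  # injected 12 bp on a plain sinusoid series
  x <- 3 * (1:10)
  series <- 0.8 + 0.1 * cos(2 * pi * x / 12)
  expect_lt(abs(periodicity(series)$period_bp - 12), 0.5)
})

test_that("flat series yield no significant period", {
  p <- periodicity(rep(0.8, 9))
  expect_true(is.na(p$period_bp))
  expect_error(periodicity(c(0.8, 0.7)), "at least 5")
})

test_that("band velocities are least-squares slopes of intensity fractions", {
  times <- 0:5
  lanes <- lapply(times, function(t) {
    f <- 0.10 + 0.01 * t   # band 2 fraction grows linearly
    g <- 0.30
    lane_profile(c(1 - f - g, g, f) * 1000 * (1 + t))  # loading varies
  })
  tc <- time_course(times, lanes)
  expect_equal(band_velocity(tc, 2), 0.01, tolerance = 1e-6)
  expect_equal(band_velocity(tc, 1), 0, tolerance = 1e-9)
  expect_equal(band_velocity(tc, 2, window = c(1, 3)), 0.01,
               tolerance = 1e-6)
  expect_error(band_velocity(tc, 2, window = c(0, 0.5)),
               "at least 2 timepoints")
  expect_error(time_course(c(0, 0), lanes[1:2]))
})

test_that("parity size extrapolates the circular efficiency trend", {
  ps <- parity_size(c(40, 80), c(0.5, 0.7), 0.9)
  expect_equal(as.numeric(ps), 120)
  expect_true(attr(ps, "extrapolated"))
  ps2 <- parity_size(c(40, 80), c(0.5, 0.7), 0.6)
  expect_equal(as.numeric(ps2), 60)
  expect_false(attr(ps2, "extrapolated"))
  # noisy points around a known line recover the crossing
  set.seed(4)
  sizes <- seq(36, 60, by = 3)
  truth <- 0.3 + 0.005 * sizes
  reps <- replicate(200, {
    eff <- truth + rnorm(length(sizes), sd = 0.01)
    as.numeric(parity_size(sizes, eff, 0.9))
  })
  expect_lt(abs(mean(reps) - 120), 3 * stats::sd(reps) / sqrt(length(reps)) + 1)
  expect_error(parity_size(c(40, 80), c(0.5, 0.5), 0.9), "zero slope")
})

test_that("lane profiles round-trip through TSV", {
  lane <- simulate_lane(n_junctions = 6, e0 = 0.8, A = 0.3,
                        n_molecules = 1e4)
  f <- tempfile(fileext = ".tsv")
  write_lane_tsv(lane, f)
  back <- read_lane_tsv(f)
  expect_equal(back$intensity, lane$intensity)
  bad <- tibble::tibble(band_index = c(0, 2), intensity = c(1, 1))
  f2 <- tempfile(fileext = ".tsv"); readr::write_tsv(bad, f2)
  expect_error(read_lane_tsv(f2), "without gaps")
})
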