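fs <- 50

test_that("the high-pass stage removes DC exactly", {
  out <- bandfilter(rep(3, 200), fs)
  expect_lt(max(abs(out)), 1e-6 * 3)
})

test_that("passband sinusoids pass with amplitude preserved", {
  t <- (0:1999) / fs
  y <- bandfilter(sin(2 * pi * 2 * t), fs)
  # steady-state amplitude away from the segment edges
  expect_equal(max(abs(y[500:1500])), 1, tolerance = 0.01)
  y2 <- bandfilter(sin(2 * pi * 2.137 * t), fs)
  expect_equal(max(abs(y2[500:1500])), 1, tolerance = 0.01)
})

test_that("stopband sinusoids are attenuated as a 12th-order cascade", {
  t <- (0:1999) / fs
  y <- bandfilter(sin(2 * pi * 20 * t), fs)
  # 20 Hz is 2.5x the 8 Hz cut-off: attenuation far beyond 97%
  expect_lt(max(abs(y[500:1500])), 0.03)
})

test_that("zero-phase filtering is equivariant under time reversal", {
  set.seed(4)
  x <- cumsum(rnorm(300))
  expect_equal(rev(bandfilter(rev(x), fs)), bandfilter(x, fs),
               tolerance = 1e-9)
})

test_that("too-short inputs are rejected", {
  expect_error(bandfilter(rnorm(20), fs), "too short")
})

test_that("segmentation crops to the half-open marker window", {
  n <- 200
  channels <- list(make_channel("chest", n), make_channel("wrist_affected", n))
  tr <- sensor_trial("WMFT-1", 1, channels, start_marker = 11,
                     end_marker = 111)
  seg <- segment_trial(tr)
  expect_identical(nrow(seg$channels[[1]]$samples), 100L)
  expect_identical(seg$start_marker, 1L)
  expect_identical(seg$end_marker, 101L)
  expect_equal(seg$channels[[1]]$samples,
               channels[[1]]$samples[11:110, ])
  # full-window markers are the identity
  full <- segment_trial(sensor_trial("WMFT-1", 1, channels))
  expect_equal(full$channels[[1]]$samples, channels[[1]]$samples)
  # unfilterably short windows are rejected
  expect_error(segment_trial(sensor_trial("WMFT-1", 1, channels,
                                          start_marker = 1,
                                          end_marker = 12)),
               "too short")
})

test_that("kinematic magnitudes integrate and differentiate correctly", {
  # passband sinusoid: velocity amplitude = A / (2 pi f)
  A <- 0.4; f <- 2
  t <- (0:999) / fs
  ch <- sensor_channel("wrist_affected",
                       cbind(bandfilter(A * sin(2 * pi * f * t), fs), 0, 0),
                       fs)
  kin <- derive_kinematics(ch)
  expect_equal(max(kin$velocity[300:700]), A / (2 * pi * f),
               tolerance = 0.03)
  # zero input -> all magnitudes identically zero
  z <- derive_kinematics(sensor_channel("chest", matrix(0, 100, 3), fs))
  expect_true(all(z$displacement == 0 & z$velocity == 0 &
                    z$acceleration == 0 & z$jerk == 0))
  # two equal orthogonal axes -> sqrt(2) times the single-axis magnitude
  x <- bandfilter(sin(2 * pi * 3 * t), fs)
  one <- derive_kinematics(sensor_channel("chest", cbind(x, 0, 0), fs))
  two <- derive_kinematics(sensor_channel("chest", cbind(x, x, 0), fs))
  expect_equal(two$acceleration, sqrt(2) * one$acceleration,
               tolerance = 1e-12)
  expect_equal(two$velocity, sqrt(2) * one$velocity, tolerance = 1e-9)
})

test_that("magnitudes are invariant under axis rotation", {
  set.seed(8)
  t <- (0:499) / fs
  m <- cbind(bandfilter(sin(2 * pi * 2 * t), fs),
             bandfilter(cos(2 * pi * 3 * t), fs),
             bandfilter(sin(2 * pi * 1.3 * t + 1), fs))
  base <- derive_kinematics(sensor_channel("chest", m, fs))
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))   # random orthonormal rotation
    rot <- derive_kinematics(sensor_channel("chest", m %*% q, fs))
    expect_equal(rot$acceleration, base$acceleration, tolerance = 1e-9)
    expect_equal(rot$jerk, base$jerk, tolerance = 1e-9)
    expect_equal(rot$velocity, base$velocity, tolerance = 1e-6)
  }
})

test_that("jerk of a linear acceleration ramp is constant in the interior", {
  a <- seq(0, 1, length.out = 200)
  ch <- sensor_channel("chest", cbind(a, 0, 0), fs)
  kin <- derive_kinematics(ch)
  interior <- kin$jerk[5:195]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-10)
  expect_equal(interior[1], (a[2] - a[1]) * fs, tolerance = 1e-10)
})
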