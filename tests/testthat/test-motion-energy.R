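test_that("motion energy counts strictly supra-threshold pixel changes", {
  a <- matrix(100L, 8, 8)
  r <- roi("p", 0, 0, 8, 8)

  # identical frames: no movement
  expect_equal(as.numeric(motion_energy(fs_of(a, a), r)), 0)

  # a change of exactly the threshold does not count; one more does
  b3 <- a; b3[2, 5] <- 103L
  b4 <- a; b4[2, 5] <- 104L
  expect_equal(as.numeric(motion_energy(fs_of(a, b3), r, threshold = 3)), 0)
  expect_equal(as.numeric(motion_energy(fs_of(a, b4), r, threshold = 3)), 1)

  # random frame pair matches the per-pixel brute-force tally
  set.seed(101)
  f1 <- matrix(sample(0:255, 64, TRUE), 8, 8)
  f2 <- matrix(sample(0:255, 64, TRUE), 8, 8)
  fs <- fs_of(f1, f2)
  expect_equal(as.numeric(motion_energy(fs, r, 3)),
               as.numeric(brute_motion_energy(fs$frames, r, 3)))
})

test_that("motion energy respects threshold monotonicity, locality and the area bound", {
  set.seed(102)
  frames <- array(sample(0:255, 12 * 12 * 6, TRUE), dim = c(12, 12, 6))
  fs <- frame_stack(frames, 25)
  r <- roi("p", 2, 2, 8, 8)

  prev <- NULL
  for (th in c(0, 3, 10, 40, 255)) {
    v <- as.numeric(motion_energy(fs, r, th))
    expect_true(all(v <= 36))  # ROI is 6x6 px
    if (!is.null(prev)) expect_true(all(v <= prev))
    prev <- v
  }

  # pixels outside the ROI never matter
  frames2 <- frames
  frames2[10:12, 10:12, ] <- sample(0:255, 9 * 6, TRUE)
  fs2 <- frame_stack(frames2, 25)
  expect_equal(as.numeric(motion_energy(fs2, r, 3)),
               as.numeric(motion_energy(fs, r, 3)))
})

test_that("motion energy validates ROI bounds and frame counts", {
  a <- matrix(100L, 8, 8)
  expect_error(motion_energy(fs_of(a, a), roi("p", 0, 0, 9, 8)),
               "exceeds frame bounds")
  expect_error(frame_stack(array(0L, dim = c(4, 4, 1)), 25), "at least 2")
  expect_error(roi("p", 4, 0, 4, 8), "x0 < x1")
})

test_that("threshold calibration returns the ceiled quantile of background change", {
  # perfectly constant background
  a <- matrix(77L, 10, 10)
  expect_equal(calibrate_threshold(fs_of(a, a, a), roi("bg", 0, 0, 10, 10)), 0)

  # iid DiscreteUniform{0..9} noise: P(|X-Y| <= 8) = .98, P(<= 9) = 1,
  # so the population 99% quantile is 9
  set.seed(103)
  n <- 21
  frames <- array(sample(0:9, 40 * 40 * n, TRUE), dim = c(40, 40, n))
  th <- calibrate_threshold(frame_stack(frames, 25), roi("bg", 0, 0, 40, 40))
  expect_equal(th, 9)

  expect_error(calibrate_threshold(fs_of(a, a), roi("bg", 0, 0, 10, 10),
                                   quantile = 1.2), "quantile")
})

test_that("gross body movement is the fraction of transitions with movement", {
  fr <- 25
  expect_equal(gross_body_movement(motion_energy_series(rep(0, 50), fr)), 0)
  expect_equal(gross_body_movement(motion_energy_series(rep(3, 50), fr)), 1)
  v <- c(rep(0, 60), rep(5, 40))
  expect_equal(gross_body_movement(motion_energy_series(v, fr)), 0.4)
  expect_error(gross_body_movement(numeric()), "empty")
})

test_that("series round-trip through CSV + sidecar is lossless", {
  s <- motion_energy_series(c(0, 4, 2, 0, 9), 25, label = "patient",
                            threshold = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_equal(as.numeric(s2), as.numeric(s))
  expect_equal(attr(s2, "frame_rate"), 25)
  expect_equal(attr(s2, "label"), "patient")
  expect_equal(attr(s2, "threshold"), 3)
})

test_that("frame directories are read with BT.601 luminance conversion", {
  dir <- withr::local_tempdir()
  set.seed(104)
  imgs <- replicate(3, array(runif(2 * 2 * 3), dim = c(2, 2, 3)),
                    simplify = FALSE)
  for (i in seq_along(imgs))
    png::writePNG(imgs[[i]], file.path(dir, sprintf("f%03d.png", i)))
  fs <- read_frames(dir, frame_rate = 25)
  expect_equal(fs$n_frames, 3)
  # luminance oracle on the first frame, pixel by pixel (PNG stores 8-bit)
  q <- round(imgs[[1]] * 255) / 255
  lum <- round(255 * (0.299 * q[, , 1] + 0.587 * q[, , 2] + 0.114 * q[, , 3]))
  expect_equal(fs$frames[, , 1], lum, ignore_attr = TRUE)
  expect_error(read_frames(dir), "frame_rate")
})

test_that("moving-median smoothing removes lone spikes and preserves length", {
  v <- rep(0, 100); v[50] <- 400
  s <- motion_energy_series(v, 25)
  sm <- smooth_series(s, 0.5)
  expect_length(sm, 100)
  expect_equal(as.numeric(sm)[50], 0)     # 13-frame median kills the spike
  expect_identical(smooth_series(s, 0), s)
})
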