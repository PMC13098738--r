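test_that("demodulation follows the three-phase arithmetic", {
  const <- matrix(2.5, 4, 4)
  st <- phase_stack(const, const, const, 851, 0.15)
  expect_true(all(demodulate(st) == 0))

  one <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  st1 <- phase_stack(one, zero, zero, 851, 0.15)
  expect_equal(demodulate(st1)[1, 1], 2 / 3, tolerance = 1e-12)

  expect_error(phase_stack(matrix(1, 2, 2), matrix(1, 2, 3), matrix(1, 2, 2),
                           851, 0.1), "same shape")
  expect_error(phase_stack(one, -one, one, 851, 0.1), "nonnegative")
  expect_error(phase_stack(one, one, one, 851, 0.1, phases = c(0, 90, 180)),
               "0, 120, 240")
})

test_that("demodulation recovers the amplitude of any three-phase sinusoid", {
  # brute-force property: random DC, amplitude, fx, phase offset, pixel grid
  set.seed(42)
  for (rep in 1:25) {
    dc <- runif(1, 0.5, 5)
    amp <- runif(1, 0.01, 1)
    fx <- runif(1, 0, 0.6)
    phi0 <- runif(1, 0, 2 * pi)
    x <- matrix(seq(0, 30, length.out = 48), 6, 8, byrow = TRUE)
    mk <- function(ph) dc + amp * sin(2 * pi * fx * x + phi0 + ph)
    st <- phase_stack(mk(0), mk(2 * pi / 3), mk(4 * pi / 3), 800, fx)
    expect_equal(max(abs(demodulate(st) - amp)), 0, tolerance = 1e-10)
  }
  # invariance to common offset, linearity under common gain
  x <- matrix(seq(0, 20, length.out = 64), 8, 8)
  mk <- function(ph) 1 + 0.3 * sin(2 * pi * 0.15 * x + ph)
  st <- phase_stack(mk(0), mk(2 * pi / 3), mk(4 * pi / 3), 800, 0.15)
  base <- demodulate(st)
  st_off <- phase_stack(st$i1 + 5, st$i2 + 5, st$i3 + 5, 800, 0.15)
  expect_equal(demodulate(st_off), base, tolerance = 1e-10)
  st_gain <- phase_stack(3 * st$i1, 3 * st$i2, 3 * st$i3, 800, 0.15)
  expect_equal(demodulate(st_gain), 3 * base, tolerance = 1e-10)
})

test_that("calibration ratios out the instrument response", {
  amp <- matrix(runif(36, 0.2, 1), 6, 6)
  m <- calibrate(amp, amp, 0.5, 851, 0.15)
  expect_true(all(abs(m$values - 0.5) < 1e-12))
  m2 <- calibrate(2 * amp, amp, 0.3, 851, 0.15)
  expect_true(all(abs(m2$values - 0.6) < 1e-12))

  # round trip on synthetic stacks sharing a response field
  resp <- matrix(runif(64, 0.4, 1.6), 8, 8)
  truth <- matrix(runif(64, 0.1, 0.9), 8, 8)
  gs <- gen_phase_stack(truth, 0.2, 811, instrument_response = resp, seed = 7)
  gp <- gen_phase_stack(matrix(0.55, 8, 8), 0.2, 811,
                        instrument_response = resp, seed = 8)
  rec <- calibrate(demodulate(gs$stack), demodulate(gp$stack), 0.55, 811, 0.2)
  expect_equal(max(abs(rec$values - truth)), 0, tolerance = 1e-10)

  # masked pixels propagate; unmasked zero phantom is an error
  pa <- amp; pa[2, 2] <- 0
  expect_error(calibrate(amp, pa, 0.5), "zero or negative")
  msk <- matrix(FALSE, 6, 6); msk[2, 2] <- TRUE
  m3 <- calibrate(amp, pa, 0.5, mask = msk)
  expect_true(is.na(m3$values[2, 2]))
  expect_equal(sum(is.na(m3$values)), 1L)
})

test_that("multiplicative corrections apply pixelwise and flag the map", {
  vals <- matrix(runif(16, 0.2, 0.8), 4, 4)
  m <- rd_map(vals, 851, 0.15)
  mi <- apply_correction(m, matrix(1, 4, 4))
  expect_identical(mi$values, vals)
  expect_true(mi$corrected)
  m2 <- apply_correction(m, matrix(2, 4, 4))
  expect_equal(m2$values, 2 * vals)
  expect_error(apply_correction(m, matrix(0, 4, 4)), "positive")

  # constructed-inverse recovery of a known cosine falloff
  tilt <- matrix(cos(seq(0, 0.8, length.out = 4)), 4, 4, byrow = TRUE)
  flat <- matrix(0.5, 4, 4)
  degraded <- rd_map(flat * tilt, 851, 0.15)
  rec <- apply_correction(degraded, 1 / tilt)
  expect_equal(max(abs(rec$values - flat)), 0, tolerance = 1e-10)
})

test_that("roi_mean averages pixels, excludes masked ones, and pools finger ROIs", {
  vals <- matrix(0.42, 900, 400)
  m <- rd_map(vals, 851, 0.15)
  expect_equal(roi_mean(m, roi_spec("forearm", c(10, 10))), 0.42)

  v2 <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  m2 <- rd_map(rbind(cbind(v2, v2), cbind(v2, v2)), 851, 0.15)
  expect_equal(roi_mean(m2, roi_spec("hand", c(0, 0), 2, 2)), 0.25)

  # five finger ROIs averaged with equal weight
  cols <- matrix(rep(c(0.1, 0.2, 0.3, 0.4, 0.5), each = 20), 4, 25)
  mf <- rd_map(cols, 851, 0.15)
  rois <- lapply(1:5, function(k)
    roi_spec(paste0("finger_", k), c(0, 5 * (k - 1)), 4, 5))
  expect_equal(roi_mean(mf, rois), 0.3, tolerance = 1e-12)

  # masked pixels are excluded; bounds are enforced
  v3 <- matrix(0.5, 4, 4); v3[1, 1] <- NA
  m3 <- rd_map(v3, 851, 0.15)
  expect_equal(roi_mean(m3, roi_spec("hand", c(0, 0), 4, 4)), 0.5)
  expect_error(roi_mean(m3, roi_spec("hand", c(2, 2), 4, 4)), "outside the image")
  v4 <- matrix(NA_real_, 2, 2)
  expect_error(roi_mean(rd_map(v4, 851, 0.15), roi_spec("hand", c(0, 0), 2, 2)),
               "only masked")
})

test_that("rd maps and phase stacks survive the TIFF round trip", {
  vals <- matrix(runif(48, 0, 1.8), 6, 8)
  vals[2, 3] <- NA
  m <- rd_map(vals, 731, 0.05, calibration_id = "ph1", corrected = TRUE)
  f <- file.path(tempdir(), "roundtrip.tif")
  write_rd_map(m, f)
  back <- read_rd_map(f)
  expect_equal(back$values, vals, tolerance = 1e-6)
  expect_equal(back$wavelength, 731)
  expect_equal(back$spatial_frequency, 0.05)
  expect_true(back$corrected)

  gs <- gen_phase_stack(matrix(0.4, 5, 7), 0.1, 691, seed = 3)
  prefix <- file.path(tempdir(), "stack1")
  write_phase_stack(gs$stack, prefix)
  st <- read_phase_stack(prefix)
  expect_equal(st$i2, gs$stack$i2, tolerance = 1e-6)
  expect_equal(st$wavelength, 691)
  expect_equal(st$spatial_frequency, 0.1)
})
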