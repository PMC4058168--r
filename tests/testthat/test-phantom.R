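test_that("phantom_config validates its inputs", {
  expect_s3_class(phantom_config("young"), "phantom_config")
  expect_error(phantom_config("young", n_cycles = 0), "n_cycles")
  expect_error(phantom_config("young", n_frames = 5, n_cycles = 3),
               "n_frames")
  expect_error(phantom_config("young", wall_intensity = 1.2), "intensities")
  expect_error(phantom_config("young", wall_row = 125, wall_thickness = 12),
               "wall_row")
  expect_error(phantom_config("young", heterogeneity = -1), "nonnegative")
  expect_error(phantom_config("young", amplitude = -1), "amplitude")
  expect_error(phantom_config("young", wave_speed = 0), "wave_speed")
  expect_error(phantom_config("bogus"))
})

test_that("category presets follow the class phenomenology", {
  expect_equal(phantom_config("young")$heterogeneity, 0)
  expect_equal(phantom_config("young")$irregularity, 0)
  expect_equal(phantom_config("cad")$heterogeneity, 1)
  expect_equal(phantom_config("cad")$irregularity, 0.5)
  # elderly walls are markedly weaker movers than young/cad ones
  expect_lt(phantom_config("elderly")$amplitude,
            phantom_config("young")$amplitude)
  # explicit arguments override presets
  expect_equal(phantom_config("elderly", amplitude = 3)$amplitude, 3)
})

test_that("generate_ecg places R peaks at uniform cycle starts", {
  ecg <- generate_ecg(120, 3)
  expect_equal(ecg$r_peaks, c(1L, 41L, 81L))
  expect_equal(generate_ecg(40, 1)$r_peaks, 1L)
  expect_error(generate_ecg(120, 0), "n_cycles")
  expect_error(generate_ecg(10, 3), "n_frames")
})

test_that("ECG samples at R peaks are the per-cycle maxima", {
  ecg <- generate_ecg(120, 3)
  cycles <- list(1:40, 41:80, 81:120)
  for (i in seq_along(cycles)) {
    expect_equal(which.max(ecg$samples[cycles[[i]]]) +
                   cycles[[i]][1] - 1L, ecg$r_peaks[i])
  }
})

count_local_maxima <- function(y) {
  n <- length(y)
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
}

test_that("motion waveforms carry the class oscillation counts", {
  u <- seq(0, 1 - 1e-9, length.out = 2000)
  expect_equal(count_local_maxima(motion_waveform("young", u)), 3)
  expect_equal(count_local_maxima(
    motion_waveform("cad", u, irregularity = 0)), 2)
  expect_equal(count_local_maxima(
    motion_waveform("elderly", u, irregularity = 0)), 2)
})

test_that("motion waveforms have unit peak and reject bad inputs", {
  u <- seq(0, 1 - 1e-9, length.out = 4096)
  for (cat_ in c("young", "elderly", "cad")) {
    expect_equal(max(abs(motion_waveform(cat_, u, irregularity = 0))), 1,
                 tolerance = 1e-6)
  }
  expect_error(motion_waveform("young", -0.1), "within")
  expect_error(motion_waveform("young", 1.5), "within")
  expect_error(motion_waveform("bogus", 0.5))
})

test_that("a zero-amplitude, noise-free phantom is a static scene", {
  ph <- generate_phantom(phantom_config("young", amplitude = 0,
                                        speckle_scale = 0, seed = 1))
  fr <- ph$sequence$frames
  for (f in 2:dim(fr)[3]) expect_identical(fr[, , f], fr[, , 1])
})

test_that("phantom generation is deterministic for a fixed seed", {
  ph1 <- generate_phantom(phantom_config("cad", seed = 7))
  ph2 <- generate_phantom(phantom_config("cad", seed = 7))
  expect_identical(ph1$sequence$frames, ph2$sequence$frames)
  expect_identical(ph1$truth$boundary, ph2$truth$boundary)
  ph3 <- generate_phantom(phantom_config("cad", seed = 8))
  expect_false(identical(ph1$sequence$frames, ph3$sequence$frames))
})

test_that("the first column's true trace equals the category waveform", {
  cfg <- phantom_config("young", seed = 1)
  ph <- generate_phantom(cfg)
  trace <- ph$truth$boundary[, 1]
  u <- ((seq_len(cfg$n_frames) - 1) %% (cfg$n_frames / cfg$n_cycles)) /
    (cfg$n_frames / cfg$n_cycles)
  s <- motion_waveform("young", u)
  expect_equal(trace - mean(trace), cfg$amplitude * (s - mean(s)),
               tolerance = 1e-9)
})

test_that("doubling amplitude doubles every trace's peak-to-peak range", {
  ph1 <- generate_phantom(phantom_config("cad", amplitude = 1, seed = 3))
  ph2 <- generate_phantom(phantom_config("cad", amplitude = 2, seed = 3))
  p2p <- function(b) apply(b, 2, function(x) diff(range(x)))
  expect_equal(p2p(ph2$truth$boundary), 2 * p2p(ph1$truth$boundary),
               tolerance = 1e-12)
})

test_that("longitudinal delay matches the configured wave speed", {
  cfg <- phantom_config("young", wave_speed = 5, seed = 1)
  ph <- generate_phantom(cfg)
  r <- ph$truth$radial
  for (pair in list(c(1, 11), c(21, 41), c(5, 35))) {
    lag <- xcorr_lag(r[, pair[1]], r[, pair[2]])
    expect_equal(lag, round((pair[2] - pair[1]) / cfg$wave_speed))
  }
})

test_that("phantom truth is internally consistent", {
  ph <- generate_phantom(phantom_config("elderly", seed = 2))
  cfg <- ph$config
  expect_true(all(ph$truth$boundary >= 1))
  expect_true(all(ph$truth$boundary + cfg$wall_thickness <= cfg$height - 1))
  # radial truth has zero temporal mean per column by construction
  expect_equal(max(abs(colMeans(ph$truth$radial))), 0, tolerance = 1e-12)
  expect_equal(dim(ph$truth$wall_mask), c(cfg$height, cfg$width))
  expect_error(
    generate_phantom(phantom_config("young", amplitude = 80, seed = 1)),
    "out of the frame")
})
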