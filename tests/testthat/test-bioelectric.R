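test_that("dipole potential matches the closed form and its symmetries", {
  # p = 1e-6 A m along z, observation 1 cm along z, sigma = 1:
  # phi = p / (4 pi sigma r^2) = 7.96e-4 V
  p <- c(0, 0, 1e-6)
  expect_equal(dipole_potential(p, c(0, 0, 0), c(0, 0, 0.01), 1),
               1e-6 / (4 * pi * 1e-4), tolerance = 1e-12)
  expect_equal(dipole_potential(p, c(0, 0, 0), c(0, 0, 0.01), 1),
               7.96e-4, tolerance = 1e-3)
  # equatorial null: displacement perpendicular to p
  expect_equal(dipole_potential(p, c(0, 0, 0), c(0.02, 0, 0), 1), 0)
  # inverse-square decay along the axis
  expect_equal(dipole_potential(p, c(0, 0, 0), c(0, 0, 0.02), 1),
               dipole_potential(p, c(0, 0, 0), c(0, 0, 0.01), 1) / 4)
  expect_error(dipole_potential(p, c(0, 0, 0), c(0, 0, 0), 1), "coincide")
})

test_that("dipole potentials superpose linearly", {
  withr::local_seed(1)
  for (i in 1:20) {
    p1 <- rnorm(3) * 1e-6; p2 <- rnorm(3) * 1e-6
    src <- rnorm(3) * 0.01; obs <- rnorm(3) * 0.05 + c(0.1, 0, 0)
    phi12 <- dipole_potential(p1 + p2, src, obs, 1)
    phi <- dipole_potential(p1, src, obs, 1) + dipole_potential(p2, src, obs, 1)
    expect_lt(abs(phi12 - phi) / max(abs(phi), 1e-30), 1e-12)
  }
})

test_that("the phantom has nine ellipsoids and the documented geometry", {
  ph <- mouse_phantom()
  expect_equal(nrow(ph$ellipsoids), 9)
  expect_equal(ph$conductivity, 1.0)
  # femoral pair geometric gain ~ 0.15 by construction
  expect_equal(electrode_pair_gain(ph), 0.15, tolerance = 0.02)
})

test_that("dipole calibration reproduces the surface amplitude and is linear", {
  ph <- mouse_phantom()
  cfg <- bio_config()
  p <- calibrate_dipole(ph, cfg)
  g <- dipole_potential(p * ph$dipole_axis, ph$heart_location / 100,
                        ph$surface_reference_point / 100, ph$conductivity)
  expect_equal(g, 1.5e-3, tolerance = 1e-10)
  cfg2 <- bio_config(ecg_surface_amp = 0.75e-3)
  expect_equal(calibrate_dipole(ph, cfg2), p / 2, tolerance = 1e-10)
})

test_that("the PQRST train has the configured rate, unit R peak and jitter", {
  cfg <- bio_config(heart_rate = 400)
  w <- ecg_waveform(cfg, duration = 30, fs = 1000, seed = 2)
  x <- w$voltage
  expect_equal(max(x), 1)
  # peak count over 30 s at 400 bpm ~ 200
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[x[peaks] > 0.5]
  expect_equal(length(peaks), 200, tolerance = 0.03)
  # mean R-R interval 0.15 s
  expect_equal(mean(diff(peaks)) / 1000, 0.15, tolerance = 0.02)
  expect_error(ecg_waveform(bio_config(heart_rate = 200), 1, 100), "\\[300, 600\\]")
})

test_that("ECG loop current is periodic at the heart rate", {
  ph <- mouse_phantom()
  cfg <- bio_config(heart_rate = 400, rr_jitter = 0)
  sp <- electrode_spec(0.5, theta = 0.1)
  lp <- loop_spec(sp)
  fs <- 1000
  v <- ecg_pair_voltage(ph, cfg, duration = 10, fs = fs, seed = 3)
  i <- bio_to_loop_current(v, lp)$current
  ac <- acf(i, lag.max = 300, plot = FALSE)$acf[-1]
  lag_peak <- which.max(ac[100:250]) + 99   # search around 0.15 s
  expect_equal(lag_peak, 0.15 * fs, tolerance = 1 / (0.15 * fs))
})

test_that("EMG bursts are Poisson-timed with a trapezoidal envelope", {
  cfg <- bio_config(emg_rate = 0.3, emg_burst_duration = 0.5)
  expect_identical(emg_bursts(bio_config(emg_rate = 0), 5, 100, 1, amp = 1)$voltage,
                   rep(0, 500))
  # expected burst count = rate * duration across 200 seeds
  counts <- vapply(1:200, function(s) {
    attr(emg_bursts(cfg, duration = 20, fs = 50, seed = s, amp = 1), "n_bursts")
  }, 0L)
  lt <- 0.3 * 20
  expect_lt(abs(mean(counts) - lt), 3 * sqrt(lt / 200))
  expect_lt(abs(var(counts) - lt), 3 * lt * sqrt(2 / 199))
  # isolated burst envelope: rises, plateaus, falls
  env <- zrasim:::trapezoid_envelope(100)
  expect_true(all(diff(env[1:20]) >= 0))
  expect_true(all(env[21:80] == 1))
  expect_true(all(diff(env[81:100]) <= 0))
})

test_that("voltage-to-current conversion matches the analytic filter response", {
  sp <- electrode_spec(0.5, theta = 0)
  lp <- loop_spec(sp, Rs = 100, Rshunt = 0)
  fs <- 1000; f0 <- 7
  t <- (0:(10 * fs - 1)) / fs
  v <- zra_trace(2e-3 * sin(2 * pi * f0 * t), fs, units = "V")
  i <- bio_to_loop_current(v, lp)$current
  mid <- i[(2 * fs):(8 * fs)]
  z0 <- loop_impedance(lp, f0)
  expect_equal(max(abs(mid)), 2e-3 / Mod(z0), tolerance = 1e-2)
  # phase: cross-correlate against the expected shifted sine
  expected <- 2e-3 / Mod(z0) * sin(2 * pi * f0 * t - Arg(z0))
  expect_gt(cor(i[(2 * fs):(8 * fs)], expected[(2 * fs):(8 * fs)]), 0.9999)
  # zero voltage -> zero current
  expect_equal(bio_to_loop_current(zra_trace(rep(0, 100), 100, units = "V"), lp)$current,
               rep(0, 100))
})
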