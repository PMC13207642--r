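make_loop <- function(area = 0.5, theta = 0.1) loop_spec(electrode_spec(area, theta = theta))

test_that("amplifier noise is white with the configured RMS", {
  inst <- instrument_spec(fs_internal = 2000)
  tr <- instrument_noise(inst, make_loop(), duration = 60, seed = 4)
  expect_equal(sd(tr$current), 0.05e-6, tolerance = 0.03)
})

test_that("Johnson noise RMS matches the Nyquist formula integrated over the band", {
  inst <- instrument_spec(amp_noise_rms = 0, fs_internal = 5000)
  lp <- make_loop()
  tr <- instrument_noise(inst, lp, duration = 60, seed = 8)
  # oracle: numerically integrate S_I(f) = 4 kB T Re(1/Zloop) to Nyquist
  f <- seq(0.5, 2500, by = 0.5)
  s <- 4 * 1.380649e-23 * 310 * Re(1 / loop_impedance(lp, f))
  rms_oracle <- sqrt(sum(s) * 0.5)
  expect_equal(sd(tr$current), rms_oracle, tolerance = 0.05)
  # all amplitudes zero -> silent instrument
  tr0 <- instrument_noise(instrument_spec(amp_noise_rms = 0, temperature = 1e-9,
                                          fs_internal = 1000),
                          lp, duration = 1, seed = 1)
  expect_lt(sd(tr0$current), 1e-15)
})

test_that("mains hum appears at the configured frequency", {
  inst <- instrument_spec(amp_noise_rms = 0, mains_freq = 50, mains_amp = 1e-6,
                          fs_internal = 1000)
  tr <- instrument_noise(inst, make_loop(), duration = 4, seed = 2)
  p <- welch_psd(tr$current, segment_length = 1000, fs = 1000)
  expect_equal(p$freq[which.max(p$psd)], 50)
})

test_that("resampling strategies behave as specified", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  # identity when rates match
  x <- sin(2 * pi * 3 * t)
  same <- resample_trace(x, adc_spec(1000, strategy = "sinc"), fs_in = fs)
  expect_equal(same$current, x)
  # 3 Hz sine under sinc to 10 Hz: amplitude preserved within 1%
  # (amplitude read as sqrt(2) * RMS over an integer number of periods)
  for (strat in c("sinc", "antialias_decimate")) {
    y <- resample_trace(x, adc_spec(10, strategy = strat), fs_in = fs)$current
    expect_equal(sqrt(2 * mean(y[11:70]^2)), 1, tolerance = 0.01)
  }
  # 6.7 Hz sine naively subsampled to 10 Hz aliases to 3.3 Hz
  xa <- sin(2 * pi * 6.7 * t)
  ya <- resample_trace(xa, adc_spec(10, strategy = "naive_subsample"), fs_in = fs)
  p <- welch_psd(ya$current, segment_length = 100, fs = 10)
  expect_equal(p$freq[which.max(p$psd)], 3.3, tolerance = 0.05)
  # and the anti-aliasing strategies suppress it instead (away from the
  # filter's edge transients)
  yf <- resample_trace(xa, adc_spec(10, strategy = "antialias_decimate"), fs_in = fs)
  expect_lt(sd(yf$current[21:80]), 0.005)
  # incommensurate rates are rejected
  expect_error(resample_trace(x, adc_spec(300), fs_in = fs), "commensurate")
})

test_that("sinc resampling preserves in-band variance (Parseval)", {
  withr::local_seed(5)
  fs <- 1000
  # band-limited noise: white noise brick-walled below 4 Hz
  w <- rnorm(20 * fs)
  xb <- zrasim:::sinc_lowpass(w, fs, 4)
  y <- resample_trace(xb, adc_spec(10, strategy = "sinc"), fs_in = fs)$current
  expect_equal(var(y), var(xb), tolerance = 0.02)
})

test_that("quantization rounds half to even, is bounded and idempotent", {
  expect_equal(quantize_trace(0.07e-6, 0.05e-6), 0.05e-6)
  # half-to-even at the tie: 0.075 / 0.05 = 1.5 -> 2, 0.125/0.05 = 2.5 -> 2
  expect_equal(quantize_trace(c(0.075e-6, 0.125e-6), 0.05e-6),
               c(0.10e-6, 0.10e-6))
  withr::local_seed(6)
  x <- rnorm(1000, sd = 1e-6)
  q <- quantize_trace(x, 0.05e-6)
  expect_lte(max(abs(q - x)), 0.025e-6 + 1e-18)
  expect_identical(quantize_trace(q, 0.05e-6), q)
  expect_identical(quantize_trace(x, 0), x)
})

test_that("assembled measurements have the documented shape and reproducibility", {
  sp <- electrode_spec(0.5, theta = 0.1)
  tr <- assemble_measurement(sp, duration = 30, seed = 1, adc = adc_spec(10))
  expect_equal(nrow(tr), 300)
  expect_equal(trace_fs(tr), 10)
  # bitwise reproducible from (config, master seed)
  tr2 <- assemble_measurement(sp, duration = 30, seed = 1, adc = adc_spec(10))
  expect_identical(tr$current, tr2$current)
  # all sources disabled -> all-zero output
  z <- assemble_measurement(sp, duration = 1, seed = 1, adc = adc_spec(10),
                            include = character(0))
  expect_identical(z$current, rep(0, 10))
})

test_that("pre-quantization total equals the sum of exported components", {
  sp <- electrode_spec(0.5, theta = 0.1)
  dec <- assemble_measurement(sp, duration = 10, seed = 3, adc = adc_spec(10),
                              decompose = TRUE)
  expect_setequal(unique(dec$component),
                  c("total", "corrosion", "ecg", "emg", "johnson", "amplifier"))
  tot <- dec$current[dec$component == "total"]
  parts <- dplyr::summarize(
    dplyr::group_by(dec[dec$component != "total", ], time),
    s = sum(current))$s
  q <- quantize_trace(parts, 0.05e-6)
  expect_equal(max(abs(tot - q)), 0, tolerance = 1e-15)
})

test_that("per-component substreams are independent of which sources are enabled", {
  sp <- electrode_spec(0.5, theta = 0.1)
  full <- assemble_measurement(sp, duration = 5, seed = 9, adc = adc_spec(10),
                               decompose = TRUE)
  corr_only <- assemble_measurement(sp, duration = 5, seed = 9, adc = adc_spec(10),
                                    include = "corrosion", decompose = TRUE)
  expect_identical(full$current[full$component == "corrosion"],
                   corr_only$current[corr_only$component == "corrosion"])
})
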