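test_that("Stern-Geary currents reproduce the hand-computed baseline values", {
  # B = 0.03 V, A = 0.5 cm^2, Rct_sp = 300 Ohm cm^2 -> 50 uA
  expect_equal(stern_geary_current(0.03, 0.5, 300), 50e-6)
  expect_equal(stern_geary_current(0.03, 0, 300), 0)
  expect_error(stern_geary_current(-0.03, 0.5, 300), ">")
  # two-zone split at theta = 0.1, A = 0.5, Rf_sp = 100:
  # bare 5 uA, coated 33.75 uA
  zc <- zone_currents(electrode_spec(0.5, theta = 0.1))
  expect_equal(zc$icorr[zc$zone == "bare"], 5e-6)
  expect_equal(zc$icorr[zc$zone == "coated"], 33.75e-6)
})

test_that("pitting noise is RMS-calibrated, 1/f^2 in-band and reproducible", {
  cfg <- corrosion_config()
  fs <- 200
  tr <- pitting_noise(50e-6, duration = 400, fs = fs, cfg, seed = 7)
  x <- tr$current
  # stationary RMS ~ 10% of Icorr within 5%
  expect_equal(sd(x), 5e-6, tolerance = 0.05)
  # log-log PSD slope between 10 * corner_f and fs/20 in [-2.3, -1.7]
  p <- welch_psd(x, segment_length = 4096, fs = fs)
  sel <- p$freq >= 10 * cfg$corner_f & p$freq <= fs / 20
  slope <- coef(lm(log10(p$psd[sel]) ~ log10(p$freq[sel])))[2]
  expect_gt(slope, -2.3)
  expect_lt(slope, -1.7)
  # identical seed -> identical trace; doubling Icorr doubles it exactly
  tr2 <- pitting_noise(50e-6, 400, fs, cfg, seed = 7)
  expect_identical(tr$current, tr2$current)
  tr3 <- pitting_noise(100e-6, 400, fs, cfg, seed = 7)
  expect_identical(tr3$current, 2 * tr$current)
})

test_that("bubble charge and detachment rate follow Faraday and the ideal gas law", {
  cfg <- corrosion_config()  # r = 20 um, T = 310 K, P = 1 atm
  # oracle recomputed from first principles
  vol <- 4 / 3 * pi * (20e-6)^3
  n_h2 <- 101325 * vol / (8.314462618 * 310)
  q_oracle <- 2 * 96485.33212 * n_h2
  expect_equal(bubble_charge(cfg)$q_bub, q_oracle, tolerance = 1e-10)
  expect_equal(q_oracle, 2.54e-7, tolerance = 2e-3)
  expect_equal(50e-6 / q_oracle, 197, tolerance = 2e-3)
})

test_that("bubble shot-noise variance matches Campbell's theorem", {
  cfg <- corrosion_config()
  fs <- 2000
  tr <- bubble_shot_noise(50e-6, duration = 100, fs = fs, cfg, seed = 3)
  q <- bubble_charge(cfg)$q_bub
  lambda <- 50e-6 / q
  # Campbell: var = lambda * integral h(t)^2 dt = lambda q^2 / (2 tau)
  v_oracle <- lambda * q^2 / (2 * cfg$tau_pulse)
  expect_equal(var(tr$current), v_oracle, tolerance = 0.10)
  expect_identical(bubble_shot_noise(0, 10, fs, cfg, seed = 1)$current,
                   rep(0, 10 * fs))
})

test_that("bubble event counts are Poisson across seeds", {
  cfg <- corrosion_config()
  q <- bubble_charge(cfg)$q_bub
  icorr <- 2e-6                       # lambda ~ 7.9 s^-1
  lt <- icorr / q * 2                 # expected count over 2 s
  counts <- vapply(1:200, function(s) {
    attr(bubble_shot_noise(icorr, 2, 500, cfg, seed = s), "n_events")
  }, 0L)
  se_mean <- sqrt(lt / 200)
  expect_lt(abs(mean(counts) - lt), 3 * se_mean)
  se_var <- lt * sqrt(2 / 199)        # approx SE of a Poisson variance estimate
  expect_lt(abs(var(counts) - lt), 3 * se_var)
})

test_that("per-zone electrode currents are independent, zero-mean and zone-tagged", {
  sp <- electrode_spec(0.5, theta = 0.1)
  ec <- electrode_current(sp, corrosion_config(), duration = 10, fs = 1e4, seed = 11)
  expect_setequal(unique(ec$zone), c("bare", "coated"))
  xb <- ec$current[ec$zone == "bare"]
  xc <- ec$current[ec$zone == "coated"]
  expect_lt(abs(cor(xb, xc)), 0.05)
  expect_lt(abs(mean(xb)), sd(xb) / 10)
  expect_equal(attr(ec, "icorr")[["bare"]], 5e-6)
  # theta = 0 leaves only the coated zone (no bare-zone source at all)
  ec0 <- electrode_current(electrode_spec(0.5, theta = 0), duration = 1,
                           fs = 1000, seed = 1)
  expect_setequal(unique(ec0$zone), "coated")
})

test_that("corrosion generators are bitwise-reproducible pure functions of seed", {
  sp <- electrode_spec(0.2, theta = 0.3)
  a <- electrode_current(sp, duration = 2, fs = 2000, seed = 99)
  b <- electrode_current(sp, duration = 2, fs = 2000, seed = 99)
  expect_identical(a$current, b$current)
  c <- electrode_current(sp, duration = 2, fs = 2000, seed = 100)
  expect_false(identical(a$current, c$current))
})

test_that("optional degradation trend ramps the zone baselines in 1-s blocks", {
  cfg <- corrosion_config(trend = list(theta_end = 0.5))
  sp <- electrode_spec(0.5, theta = 0.1)
  ec <- electrode_current(sp, cfg, duration = 10, fs = 100, seed = 5)
  bare <- ec$current[ec$zone == "bare"]
  # the bare zone grows as theta ramps 0.1 -> 0.5: last second clearly
  # above the first second on average
  expect_gt(mean(bare[901:1000]) - mean(bare[1:100]), 1e-6)
  # trend off -> zero-mean
  ec0 <- electrode_current(sp, corrosion_config(), duration = 10, fs = 100, seed = 5)
  expect_lt(abs(mean(ec0$current[ec0$zone == "bare"])),
            sd(ec0$current[ec0$zone == "bare"]))
})
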