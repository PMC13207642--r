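test_that("element impedance laws hold for the primitive elements", {
  f <- c(0.1, 1, 10, 1000)
  expect_equal(ckt_impedance(ckt_resistor(600), f), rep(600 + 0i, 4))
  expect_equal(ckt_impedance(ckt_capacitor(1e-6), 1),
               1 / (2i * pi * 1e-6))
  # CPE with n = 1 is an ideal capacitor with C = Q
  expect_equal(ckt_impedance(ckt_cpe(3e-5, 1), f),
               ckt_impedance(ckt_capacitor(3e-5), f))
  expect_equal(ckt_impedance(ckt_inductor(1e-3), 10), 2i * pi * 10 * 1e-3)
  expect_equal(ckt_impedance(ckt_warburg(50), 2), 50 * (1 - 1i) / sqrt(4 * pi))
  # series adds, parallel halves
  expect_equal(ckt_impedance(ckt_series(ckt_resistor(300), ckt_resistor(300)), 1),
               600 + 0i)
  expect_equal(ckt_impedance(ckt_parallel(ckt_resistor(300), ckt_resistor(300)), 1),
               150 + 0i)
})

test_that("parameter validation and DC-singularity domain errors fire", {
  expect_error(ckt_resistor(-5), "positive")
  expect_error(ckt_cpe(1e-5, 1.2), "0, 1")
  expect_error(ckt_impedance(ckt_cpe(1e-5, 0.8), 0), "singular")
  expect_error(ckt_impedance(ckt_warburg(10), c(1, 0)), "singular")
  # ideal capacitor at DC is an open circuit, not an error
  expect_true(is.infinite(Mod(ckt_impedance(ckt_capacitor(1e-6), 0))))
})

test_that("series/parallel algebra agrees with the brute-force nodal solver", {
  withr::local_seed(42)
  f <- 10^seq(-1, 3, length.out = 20)
  for (i in 1:12) {
    tree <- random_tree(sample(2:8, 1))
    za <- ckt_impedance(tree, f)
    zb <- graph_impedance(tree, f)
    expect_lt(max(Mod(za - zb) / Mod(zb)), 1e-9)
  }
})

test_that("two-zone electrode impedance matches hand-derived DC values", {
  # theta = 0: coated single zone, DC limit (Rf + Rct) / A
  sp0 <- electrode_spec(0.5, Rct_sp = 300, Rf_sp = 100, Cf_sp = 800e-6, theta = 0)
  expect_equal(Re(electrode_impedance(sp0, 0)), (100 + 300) / 0.5, tolerance = 1e-12)
  # theta = 0.1: (400/0.45) || (300/0.05) = 774.19 Ohm
  sp <- electrode_spec(0.5, theta = 0.1)
  z <- electrode_impedance(sp, 0)
  expect_equal(Re(z), 1 / (0.45 / 400 + 0.05 / 300), tolerance = 1e-12)
  expect_equal(Re(z), 774.1935, tolerance = 1e-4)
  # theta = 1 equals the bare electrode, coating ignored
  sp1 <- electrode_spec(0.5, theta = 1)
  bare <- electrode_spec(0.5, Rf_sp = NULL, Cf_sp = NULL)
  ff <- c(0.01, 1, 100)
  expect_equal(electrode_impedance(sp1, ff), electrode_impedance(bare, ff))
})

test_that("two-zone impedance is continuous in theta at the endpoints", {
  f <- c(0.1, 5, 50)
  for (th in c(1e-9, 1 - 1e-9)) {
    sp_eps <- electrode_spec(0.5, theta = th)
    sp_lim <- electrode_spec(0.5, theta = round(th))
    expect_equal(electrode_impedance(sp_eps, f), electrode_impedance(sp_lim, f),
                 tolerance = 1e-6)
  }
})

test_that("loop impedance follows Rs + 2 Ze + Rshunt and its limits", {
  sp <- electrode_spec(0.5, theta = 0)
  lp <- loop_spec(sp, Rs = 500, Rshunt = 100)
  expect_equal(Re(loop_impedance(lp, 0)), 500 + 2 * 800 + 100)
  lp0 <- loop_spec(sp, Rs = 0, Rshunt = 0)
  expect_equal(loop_impedance(lp0, 3), 2 * electrode_impedance(sp, 3))
  # ideal capacitors short at high frequency: Zloop -> Rs + Rshunt
  expect_equal(Mod(loop_impedance(lp, 1e9)), 600, tolerance = 1e-3)
  # |Zloop| non-increasing in f for the R||C two-time-constant topology
  f <- 10^seq(-3, 4, length.out = 60)
  m <- Mod(loop_impedance(lp0, f))
  expect_true(all(diff(m) <= 1e-9))
})

test_that("disk spreading resistance follows rho / (4 r)", {
  r <- sqrt(0.5 / pi)
  expect_equal(spreading_resistance(0.5, 100), 100 / (4 * r))
  expect_equal(spreading_resistance(0.5, 100), 62.67, tolerance = 1e-3)
  # quadrupling the area halves the per-electrode value
  expect_equal(spreading_resistance(2.0, 100), spreading_resistance(0.5, 100) / 2)
  expect_equal(spreading_resistance(1, 0), 0)
  expect_error(spreading_resistance(-1, 100), "positive")
})

test_that("single-zone transfer gains equal Ze/Zloop and 1/Zloop exactly", {
  sp <- electrode_spec(0.5, theta = 0)
  lp <- loop_spec(sp, Rs = 120, Rshunt = 30)
  tp <- transfer_paths(lp)
  f <- 10^seq(-2, 3, length.out = 15)
  expect_equal(tp$corrosion_coated(f),
               electrode_impedance(sp, f) / loop_impedance(lp, f),
               tolerance = 1e-12)
  expect_equal(tp$bio_voltage(f), 1 / loop_impedance(lp, f), tolerance = 1e-12)
  # bio gain at DC: 1 mV across 2200 Ohm -> 0.4545 uA
  lp2 <- loop_spec(sp, Rs = 500, Rshunt = 100)
  expect_equal(1e-3 * Mod(transfer_paths(lp2)$bio_voltage(1e-9)),
               0.4545e-6, tolerance = 1e-3)
})

test_that("two-zone corrosion gains match the brute-force nodal solver", {
  f <- 10^seq(-2, 3, length.out = 12)
  for (th in c(0.05, 0.3, 0.8)) {
    sp <- electrode_spec(0.4, theta = th)
    for (rs in c(0, 250)) {
      lp <- loop_spec(sp, Rs = rs, Rshunt = 10)
      tp <- transfer_paths(lp)
      oracle <- nodal_corrosion_gain(lp, f)
      for (g in tp[startsWith(names(tp), "corrosion_")]) {
        expect_equal(g(f), oracle, tolerance = 1e-9)
        # gains bounded by the DC resistive-divider value
        expect_true(all(Mod(g(f)) <= Mod(g(1e-9)) + 1e-9))
      }
    }
  }
})

test_that("electrode validation rejects inconsistent specifications", {
  expect_error(electrode_spec(0.5, Rf_sp = 100, Cf_sp = NULL), "together")
  expect_error(electrode_spec(0.5, Rf_sp = NULL, Cf_sp = NULL, theta = 0.2),
               "requires coating")
  expect_error(electrode_spec(0.5, theta = 1.2), "\\[0, 1\\]")
  expect_error(electrode_spec(-0.5), "positive")
})
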