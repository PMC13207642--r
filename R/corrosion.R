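#' Corrosion noise configuration
#'
#' Parameters of the electrochemical noise model. The baseline corrosion
#' current of each zone follows the Stern-Geary relation
#' `Icorr = B * area / Rsp`; on top of it the model generates 1/f^2
#' metastable-pitting noise (a stationary Ornstein-Uhlenbeck process with a
#' low corner frequency, RMS-calibrated to `pitting_fraction * Icorr`) and
#' hydrogen-bubble shot noise (a Poisson train of exponential pulses, each
#' carrying the Faraday charge of one critical-size bubble).
#'
#' @param B Stern-Geary coefficient, V.
#' @param pitting_fraction pitting-noise RMS as a fraction of `Icorr`.
#' @param r_bub critical bubble radius, m (20 um default).
#' @param tau_pulse bubble pulse RC smoothing time constant, s. The default
#'   is the interface time constant `Rct_sp * Cdl_sp` = 300 * 25e-6 = 7.5 ms.
#' @param corner_f pitting-noise stationarity corner frequency, Hz; the PSD
#'   is flat below and falls as 1/f^2 above.
#' @param trend optional list `list(theta_end = ...)`: a linear ramp of the
#'   breach fraction over the recording, re-evaluated in 1-s blocks, added as
#'   a deterministic drift of the zone baseline currents. `NULL` disables.
#' @param temperature temperature, K.
#' @param pressure ambient pressure, atm.
#' @return an object of class `zra_corrosion_config`.
#' @export
corrosion_config <- function(B = 0.03, pitting_fraction = 0.10,
                             r_bub = 20e-6, tau_pulse = 7.5e-3,
                             corner_f = 0.1, trend = NULL,
                             temperature = 310, pressure = 1) {
  .check_pos(B, "B"); .check_pos(r_bub, "r_bub"); .check_pos(tau_pulse, "tau_pulse")
  .check_pos(corner_f, "corner_f"); .check_pos(temperature, "temperature")
  .check_pos(pressure, "pressure")
  if (!is.numeric(pitting_fraction) || pitting_fraction <= 0 || pitting_fraction >= 1) {
    abort("`pitting_fraction` must lie in (0, 1).")
  }
  structure(list(B = B, pitting_fraction = pitting_fraction, r_bub = r_bub,
                 tau_pulse = tau_pulse, corner_f = corner_f, trend = trend,
                 temperature = temperature, pressure = pressure),
            class = "zra_corrosion_config")
}

#' Stern-Geary baseline corrosion current
#'
#' `I = B * area / Rsp`. For the two-zone breach model the bare zone uses
#' `(A * theta, Rct_sp)` and the coated zone `(A * (1 - theta),
#' Rct_sp + Rf_sp)`; see [zone_currents()].
#'
#' @param B Stern-Geary coefficient, V.
#' @param area zone area, cm^2 (may be 0 for an empty zone).
#' @param Rsp area-specific polarization resistance of the current path,
#'   Ohm cm^2.
#' @return corrosion current, A.
#' @export
stern_geary_current <- function(B, area, Rsp) {
  if (any(B <= 0) || any(Rsp <= 0) || any(area < 0)) {
    abort("`B` and `Rsp` must be > 0 and `area` >= 0.")
  }
  B * area / Rsp
}

#' Per-zone baseline corrosion currents of a breached electrode
#'
#' @param spec an [electrode_spec()].
#' @param cfg a [corrosion_config()].
#' @return tibble with columns `zone`, `area` (cm^2), `Rsp` (Ohm cm^2) and
#'   `icorr` (A).
#' @export
zone_currents <- function(spec, cfg = corrosion_config()) {
  zones <- electrode_zones(spec)
  areas <- unname(vapply(zones, `[[`, 0, "area"))
  rsp <- unname(vapply(names(zones), function(z) {
    if (z == "bare") spec$Rct_sp else spec$Rct_sp + spec$Rf_sp
  }, 0))
  tibble(zone = names(zones), area = areas, Rsp = rsp,
         icorr = stern_geary_current(cfg$B, areas, rsp))
}

## Unit-RMS stationary AR(1) (discrete Ornstein-Uhlenbeck) sample path.
## a = exp(-2 pi f_c / fs) gives a Lorentzian PSD with corner f_c: flat
## below, 1/f^2 above.
ou_unit_path <- function(n, fs, corner_f, seed) {
  a <- exp(-2 * pi * corner_f / fs)
  with_seed(seed, {
    x0 <- rnorm(1)
    innov <- rnorm(n - 1, sd = sqrt(1 - a^2))
    as.numeric(stats::filter(c(x0, innov), a, method = "recursive", init = 0))
  })
}

#' Metastable pitting noise (1/f^2)
#'
#' Zero-mean stationary leaky-integrator (Ornstein-Uhlenbeck) process whose
#' PSD is flat below `corner_f` and falls as 1/f^2 above it, with stationary
#' RMS calibrated to `pitting_fraction * Icorr`. A pure random walk (exact
#' 1/f^2 at all frequencies) is nonstationary; the low corner keeps each
#' recording stationary while preserving the 1/f^2 regime in-band.
#'
#' The trace is an exact linear function of `Icorr` at fixed seed, so
#' doubling `Icorr` doubles the RMS sample-by-sample.
#'
#' @param Icorr baseline corrosion current, A.
#' @param duration record length, s.
#' @param fs sampling rate, Hz.
#' @param cfg a [corrosion_config()].
#' @param seed integer seed.
#' @return a [zra_trace()] of current fluctuations, A.
#' @export
pitting_noise <- function(Icorr, duration, fs, cfg = corrosion_config(), seed = 1) {
  if (Icorr < 0) abort("`Icorr` must be >= 0.")
  n <- as.integer(round(duration * fs))
  if (n < 2) abort("`duration * fs` must be at least 2 samples.")
  x <- ou_unit_path(n, fs, cfg$corner_f, seed) * cfg$pitting_fraction * Icorr
  zra_trace(x, fs, label = "pitting")
}

#' Faraday charge and detachment rate of hydrogen bubbles
#'
#' One critical bubble of radius `r_bub` holds `n = P V / (R T)` moles of
#' H2 and therefore carries `q = 2 F n` coulombs of cathodic charge
#' (2 electrons per H2). A cathodic current `I` then detaches bubbles at
#' rate `lambda = I / q`.
#'
#' @param cfg a [corrosion_config()].
#' @return list with `q_bub` (C per bubble) and `vol` (m^3).
#' @export
bubble_charge <- function(cfg = corrosion_config()) {
  vol <- 4 / 3 * pi * cfg$r_bub^3
  n_h2 <- cfg$pressure * .const$atm * vol / (.const$R_gas * cfg$temperature)
  list(q_bub = 2 * .const$faraday * n_h2, vol = vol)
}

#' Hydrogen-bubble shot noise
#'
#' Poisson pulse train: bubble detachments occur at rate
#' `lambda = I_cathodic / q_bub`; each detachment injects an exponentially
#' decaying current pulse of time constant `tau_pulse` (the double-layer RC
#' smoothing) carrying exactly the bubble charge `q_bub`. The returned trace
#' is mean-removed (the DC component is part of the Stern-Geary baseline).
#'
#' @param I_cathodic cathodic current feeding hydrogen evolution, A.
#' @inheritParams pitting_noise
#' @return a [zra_trace()] of current fluctuations, A.
#' @export
bubble_shot_noise <- function(I_cathodic, duration, fs, cfg = corrosion_config(), seed = 1) {
  if (I_cathodic < 0) abort("`I_cathodic` must be >= 0.")
  n <- as.integer(round(duration * fs))
  if (n < 2) abort("`duration * fs` must be at least 2 samples.")
  if (I_cathodic == 0) return(zra_trace(rep(0, n), fs, label = "bubbles"))
  q <- bubble_charge(cfg)$q_bub
  lambda <- I_cathodic / q
  a <- exp(-1 / (fs * cfg$tau_pulse))
  ## discrete pulse amplitude chosen so each event integrates to exactly q
  amp <- q * (1 - a) * fs
  warm <- as.integer(ceiling(5 * cfg$tau_pulse * fs))
  gen <- with_seed(seed, {
    counts <- rpois(n + warm, lambda / fs)
    list(x = as.numeric(stats::filter(counts * amp, a, method = "recursive")),
         n_events = sum(counts[(warm + 1):(warm + n)]))
  })
  n_events <- gen$n_events
  x <- gen$x[(warm + 1):(warm + n)]
  out <- zra_trace(x - mean(x), fs, label = "bubbles")
  attr(out, "n_events") <- n_events
  attr(out, "rate") <- lambda
  out
}

#' Per-zone corrosion current fluctuations
#'
#' Generates the corrosion fluctuation trace of each populated zone of a
#' (possibly breached) electrode: independent pitting and bubble noise per
#' zone, plus the optional slow degradation trend. In the symmetric
#' two-electrode ZRA pair the identical deterministic baselines cancel in
#' expectation, so only fluctuations are propagated into the loop; the
#' baselines are reported in the `icorr` attribute.
#'
#' Per-zone seeds are derived deterministically from `seed`, so the bare and
#' coated zones are independent and each is reproducible in isolation.
#'
#' @param spec an [electrode_spec()].
#' @param cfg a [corrosion_config()].
#' @param duration record length, s.
#' @param fs sampling rate, Hz.
#' @param seed master integer seed.
#' @return a long tibble with columns `time`, `zone`, `current` (A) and
#'   attributes `fs` and `icorr` (named baseline currents, A).
#' @export
electrode_current <- function(spec, cfg = corrosion_config(), duration, fs, seed = 1) {
  zc <- zone_currents(spec, cfg)
  n <- as.integer(round(duration * fs))
  pieces <- lapply(seq_len(nrow(zc)), function(i) {
    zone <- zc$zone[i]
    ic <- zc$icorr[i]
    pit <- trace_samples(pitting_noise(ic, duration, fs, cfg,
                                       substream_seed(seed, paste0("pitting-", zone))))
    bub <- trace_samples(bubble_shot_noise(ic, duration, fs, cfg,
                                           substream_seed(seed, paste0("bubbles-", zone))))
    x <- pit + bub + zone_trend(spec, cfg, zone, duration, fs)
    tibble(time = (seq_len(n) - 1) / fs, zone = zone, current = x)
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "fs") <- fs
  attr(out, "icorr") <- stats::setNames(zc$icorr, zc$zone)
  out
}

## Deterministic degradation trend: baseline current drift of one zone as
## theta ramps linearly to cfg$trend$theta_end, stepped in 1-s blocks.
zone_trend <- function(spec, cfg, zone, duration, fs) {
  n <- as.integer(round(duration * fs))
  if (is.null(cfg$trend) || !spec$coated) return(rep(0, n))
  theta_end <- cfg$trend$theta_end
  if (is.null(theta_end) || theta_end < 0 || theta_end > 1) {
    abort("`trend$theta_end` must be a breach fraction in [0, 1].")
  }
  blocks <- pmin(floor((seq_len(n) - 1) / fs), max(1, floor(duration)) - 1)
  th <- spec$theta + (theta_end - spec$theta) * blocks / max(1, floor(duration) - 1)
  base <- if (zone == "bare") {
    stern_geary_current(cfg$B, spec$area * spec$theta, spec$Rct_sp)
  } else {
    stern_geary_current(cfg$B, spec$area * (1 - spec$theta), spec$Rct_sp + spec$Rf_sp)
  }
  now <- if (zone == "bare") {
    stern_geary_current(cfg$B, spec$area * th, spec$Rct_sp)
  } else {
    stern_geary_current(cfg$B, spec$area * (1 - th), spec$Rct_sp + spec$Rf_sp)
  }
  now - base
}
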