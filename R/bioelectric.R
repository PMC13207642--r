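#' Nine-ellipsoid mouse phantom
#'
#' Anatomical phantom of the mouse body: nine oriented ellipsoids (torso,
#' thorax, head, two ears, four limbs) giving a 3D geometry for electrode
#' placement, plus a homogeneous volume-conductor conductivity. The
#' ellipsoids define geometry and placement only; potentials are computed in
#' an unbounded homogeneous conductor, so no boundary correction is applied.
#'
#' Coordinates are centimetres; the body axis runs along +x (nose at the
#' origin end), +z is dorsal. The cardiac dipole sits in the thorax, tilted
#' 30 degrees off the body axis; the surface reference point used to
#' calibrate the dipole magnitude lies on the ventral chest wall. The
#' default electrode pair is the femoral implant site on a hind limb, placed
#' so the pair's differential geometric gain is about 0.15 of the surface
#' ECG amplitude.
#'
#' @param conductivity tissue conductivity, S/m.
#' @return object of class `zra_phantom`: list with `ellipsoids` (tibble),
#'   `conductivity`, `heart_location`, `dipole_axis`,
#'   `surface_reference_point` and `electrode_sites` (named list of 3x2
#'   matrices, columns = the two electrodes, cm).
#' @export
mouse_phantom <- function(conductivity = 1.0) {
  if (!is.numeric(conductivity) || conductivity <= 0) {
    abort("`conductivity` must be > 0.")
  }
  ell <- tibble(
    name = c("torso", "thorax", "head", "ear_l", "ear_r",
             "limb_fl", "limb_fr", "limb_hl", "limb_hr"),
    cx = c(4.5, 2.6, 0.8, 0.5, 0.5, 2.2, 2.2, 6.2, 6.2),
    cy = c(0, 0, 0, 0.8, -0.8, 1.0, -1.0, 1.0, -1.0),
    cz = c(0, 0.2, 0.5, 1.3, 1.3, -0.8, -0.8, -0.9, -0.9),
    ax = c(3.5, 1.4, 1.25, 0.4, 0.4, 1.5, 1.5, 1.5, 1.5),
    ay = c(1.25, 1.1, 0.9, 0.3, 0.3, 0.4, 0.4, 0.4, 0.4),
    az = c(1.1, 1.0, 0.9, 0.15, 0.15, 0.4, 0.4, 0.4, 0.4),
    tilt_deg = c(0, 0, 10, 0, 0, 25, 25, 25, 25)
  )
  heart <- c(2.6, 0, 0.2)
  axis <- c(cos(pi / 6), 0, -sin(pi / 6))
  sites <- list(
    femoral = cbind(heart + c(2.5, 0.4, 0), heart + c(3.5, 0.4, 0)),
    chest   = cbind(heart + c(-0.5, 0.9, -0.6), heart + c(0.5, 0.9, -0.6))
  )
  structure(list(ellipsoids = ell, conductivity = conductivity,
                 heart_location = heart, dipole_axis = axis / sqrt(sum(axis^2)),
                 surface_reference_point = heart + c(0, 0, -1.082),
                 electrode_sites = sites),
            class = "zra_phantom")
}

#' @export
print.zra_phantom <- function(x, ...) {
  cat(sprintf("<zra_phantom> %d ellipsoids, conductivity %g S/m\n",
              nrow(x$ellipsoids), x$conductivity))
  cat(sprintf("  heart at (%.2f, %.2f, %.2f) cm; sites: %s\n",
              x$heart_location[1], x$heart_location[2], x$heart_location[3],
              paste(names(x$electrode_sites), collapse = ", ")))
  invisible(x)
}

#' Potential of a current dipole in a homogeneous volume conductor
#'
#' \deqn{\varphi = \frac{\mathbf p \cdot (\mathbf r_{obs} - \mathbf r_{src})}
#'   {4 \pi \sigma |\mathbf r_{obs} - \mathbf r_{src}|^3}}
#'
#' @param p_vec dipole moment vector, A m.
#' @param r_src source position, m.
#' @param r_obs observation position, m.
#' @param sigma conductivity, S/m.
#' @return potential, V.
#' @export
dipole_potential <- function(p_vec, r_src, r_obs, sigma) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  d <- r_obs - r_src
  r <- sqrt(sum(d^2))
  if (r == 0) abort("observation point coincides with the dipole source.")
  sum(p_vec * d) / (4 * pi * sigma * r^3)
}

## Unit-moment gain (V per A m) from the phantom's heart dipole to a point
## given in phantom (cm) coordinates.
unit_dipole_gain <- function(phantom, point_cm) {
  dipole_potential(phantom$dipole_axis,
                   phantom$heart_location / 100, point_cm / 100,
                   phantom$conductivity)
}

#' Bioelectric interference configuration
#'
#' @param heart_rate heart rate, bpm; murine range `[300, 600]`.
#' @param ecg_surface_amp target R-peak amplitude at the body-surface
#'   reference point, V.
#' @param emg_rate EMG burst rate, bursts/s.
#' @param emg_amp plateau RMS of one EMG burst at the electrode pair, V;
#'   `NULL` defaults to one quarter of the ECG pair peak-to-peak amplitude
#'   (bursts "comparable to ECG").
#' @param emg_burst_duration burst length, s.
#' @param dipole_moment cardiac dipole moment, A m; `NULL` means calibrate
#'   with [calibrate_dipole()].
#' @param rr_jitter fractional standard deviation of beat-to-beat R-R
#'   interval variation.
#' @return object of class `zra_bio_config`.
#' @export
bio_config <- function(heart_rate = 400, ecg_surface_amp = 1.5e-3,
                       emg_rate = 0.3, emg_amp = NULL,
                       emg_burst_duration = 0.5, dipole_moment = NULL,
                       rr_jitter = 0.03) {
  if (!is.numeric(heart_rate) || heart_rate < 300 || heart_rate > 600) {
    abort("`heart_rate` must lie in [300, 600] bpm.")
  }
  if (ecg_surface_amp < 0 || emg_rate < 0 || emg_burst_duration <= 0) {
    abort("bioelectric amplitudes and rates must be >= 0.")
  }
  structure(list(heart_rate = heart_rate, ecg_surface_amp = ecg_surface_amp,
                 emg_rate = emg_rate, emg_amp = emg_amp,
                 emg_burst_duration = emg_burst_duration,
                 dipole_moment = dipole_moment, rr_jitter = rr_jitter),
            class = "zra_bio_config")
}

#' Calibrate the cardiac dipole moment
#'
#' The dipole potential is linear in the moment, so the moment that makes
#' the R-peak potential at the phantom's surface reference point equal to
#' `ecg_surface_amp` is found in one step.
#'
#' @param phantom a [mouse_phantom()].
#' @param cfg a [bio_config()].
#' @return dipole moment, A m.
#' @export
calibrate_dipole <- function(phantom, cfg = bio_config()) {
  g <- unit_dipole_gain(phantom, phantom$surface_reference_point)
  if (abs(g) < 1e-12) {
    abort("reference point lies on the dipole equator; cannot calibrate.")
  }
  cfg$ecg_surface_amp / g
}

#' Differential geometric gain of an electrode pair
#'
#' Ratio of the pair's differential dipole potential to the potential at the
#' body-surface reference point (both per unit moment). With the default
#' phantom geometry the femoral pair has a gain of about 0.15.
#'
#' @param phantom a [mouse_phantom()].
#' @param site electrode site name (default `"femoral"`).
#' @return dimensionless gain.
#' @export
electrode_pair_gain <- function(phantom, site = "femoral") {
  pts <- phantom$electrode_sites[[site]]
  if (is.null(pts)) abort(paste0("unknown electrode site '", site, "'"))
  g1 <- unit_dipole_gain(phantom, pts[, 1])
  g2 <- unit_dipole_gain(phantom, pts[, 2])
  gr <- unit_dipole_gain(phantom, phantom$surface_reference_point)
  (g1 - g2) / gr
}

#' Normalized PQRST waveform train
#'
#' Parametric sum-of-Gaussians PQRST beat template repeated at the
#' configured heart rate with small beat-to-beat R-R jitter, normalized so
#' the R peak equals 1 before any amplitude scaling.
#'
#' @param cfg a [bio_config()].
#' @param duration record length, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed (controls R-R jitter).
#' @return a dimensionless [zra_trace()] (`units = "V"` after scaling by the
#'   caller; here unitless, stored in the voltage column).
#' @export
ecg_waveform <- function(cfg = bio_config(), duration, fs, seed = 1) {
  rr0 <- 60 / cfg$heart_rate
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  ## beat times with multiplicative jitter
  rpeaks <- with_seed(seed, {
    k <- as.integer(ceiling(duration / rr0)) + 3L
    rr <- rr0 * pmax(0.5, 1 + cfg$rr_jitter * rnorm(k))
    cumsum(c(rr0 / 2, rr[-1]))
  })
  rpeaks <- rpeaks[rpeaks < duration + 0.1]
  ## PQRST template: (offset ms, amplitude, sd ms), scaled to a 150 ms beat
  waves <- cbind(off = c(-45, -8, 0, 7, 35) * 1e-3 * (rr0 / 0.15),
                 amp = c(0.15, -0.10, 1.00, -0.15, 0.30),
                 sdv = c(8, 3, 4, 3, 12) * 1e-3 * (rr0 / 0.15))
  x <- numeric(n)
  for (tp in rpeaks) {
    for (w in seq_len(nrow(waves))) {
      mu <- tp + waves[w, "off"]; s <- waves[w, "sdv"]
      i1 <- max(1L, as.integer(floor((mu - 6 * s) * fs)))
      i2 <- min(n, as.integer(ceiling((mu + 6 * s) * fs)))
      if (i1 > n || i2 < 1) next
      idx <- i1:i2
      x[idx] <- x[idx] + waves[w, "amp"] * exp(-(t[idx] - mu)^2 / (2 * s^2))
    }
  }
  m <- max(abs(x))
  if (m > 0) x <- x / m
  zra_trace(x, fs, label = "ecg", units = "V")
}

#' ECG voltage at an electrode pair
#'
#' The PQRST train scaled by the calibrated dipole moment and the pair's
#' differential dipole gain: the open-circuit interference voltage that
#' drives current through the measurement loop.
#'
#' @inheritParams ecg_waveform
#' @param phantom a [mouse_phantom()].
#' @param site electrode site name.
#' @return a voltage [zra_trace()], V.
#' @export
ecg_pair_voltage <- function(phantom, cfg = bio_config(), duration, fs,
                             seed = 1, site = "femoral") {
  p <- cfg$dipole_moment %||% calibrate_dipole(phantom, cfg)
  pts <- phantom$electrode_sites[[site]]
  if (is.null(pts)) abort(paste0("unknown electrode site '", site, "'"))
  gdiff <- unit_dipole_gain(phantom, pts[, 1]) - unit_dipole_gain(phantom, pts[, 2])
  w <- ecg_waveform(cfg, duration, fs, seed)
  zra_trace(trace_samples(w) * p * gdiff, fs, label = "ecg", units = "V")
}

## Peak-to-peak ECG voltage at the electrode pair (jitter-free template),
## used as the reference scale for the default EMG burst amplitude.
ecg_pair_pkpk <- function(phantom, cfg = bio_config(), site = "femoral") {
  p <- cfg$dipole_moment %||% calibrate_dipole(phantom, cfg)
  pts <- phantom$electrode_sites[[site]]
  gdiff <- unit_dipole_gain(phantom, pts[, 1]) - unit_dipole_gain(phantom, pts[, 2])
  cfg0 <- cfg; cfg0$rr_jitter <- 0
  w <- trace_samples(ecg_waveform(cfg0, 2 * 60 / cfg$heart_rate, 2000, seed = 1))
  abs(p * gdiff) * (max(w) - min(w))
}

#' EMG burst interference voltage
#'
#' Poisson-timed bursts of broadband (white) noise shaped by a trapezoidal
#' envelope (20% rise, 60% plateau, 20% fall of the burst duration).
#'
#' @inheritParams ecg_waveform
#' @param amp plateau RMS amplitude of one burst, V (overrides
#'   `cfg$emg_amp`).
#' @return a voltage [zra_trace()], V.
#' @export
emg_bursts <- function(cfg = bio_config(), duration, fs, seed = 1, amp = NULL) {
  if (cfg$emg_rate < 0) abort("`emg_rate` must be >= 0.")
  n <- as.integer(round(duration * fs))
  a <- amp %||% cfg$emg_amp
  if (is.null(a)) abort("EMG amplitude not set; give `amp` or `cfg$emg_amp`.")
  x <- numeric(n)
  k <- 0L
  if (cfg$emg_rate > 0 && a > 0) {
    nb <- as.integer(round(cfg$emg_burst_duration * fs))
    env <- trapezoid_envelope(nb)
    gen <- with_seed(seed, {
      k <- rpois(1, cfg$emg_rate * duration)
      starts <- sort(as.integer(floor(runif(k, 0, n - 1))) + 1L)
      for (s in starts) {
        idx <- s:min(n, s + nb - 1L)
        x[idx] <- x[idx] + a * rnorm(length(idx)) * env[seq_along(idx)]
      }
      list(x = x, k = k)
    })
    x <- gen$x; k <- gen$k
  }
  out <- zra_trace(x, fs, label = "emg", units = "V")
  attr(out, "n_bursts") <- k
  out
}

trapezoid_envelope <- function(n) {
  i <- seq_len(n)
  r <- max(1L, as.integer(round(0.2 * n)))
  env <- rep(1, n)
  env[i <= r] <- i[i <= r] / r
  env[i > n - r] <- (n - i[i > n - r] + 1) / r
  env
}

#' Convert a bioelectric voltage trace to loop current
#'
#' Frequency-domain filtering `I(f) = V(f) / Zloop(f)`: the interference
#' voltage across the electrode pair drives current through the full loop
#' impedance.
#'
#' @param v a voltage [zra_trace()].
#' @param loop a [loop_spec()].
#' @return a current [zra_trace()], A.
#' @export
bio_to_loop_current <- function(v, loop) {
  fs <- trace_fs(v)
  gain <- transfer_paths(loop)$bio_voltage
  x <- apply_freq_gain(trace_samples(v), fs, gain)
  zra_trace(x, fs, label = paste0(attr(v, "label") %||% "bio"), units = "A")
}
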